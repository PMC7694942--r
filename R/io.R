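#' @include AllClasses.R accessors.R
NULL

## Writers emit plain TSV plus a small JSON sidecar recording how the file
## was produced, so a cohort directory is self-describing.

writeSidecar <- function(path, what, extra = list()) {
    meta <- c(list(format = what,
                   producer = paste0("immunotype ",
                                     as.character(utils::packageVersion("immunotype")))),
              extra)
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' Read a genes x samples expression matrix from TSV
#'
#' Expects tab-separated text with the gene symbol in the first column and a
#' header row of sample identifiers. Rows with any missing value are dropped
#' (and counted); duplicate gene rows are collapsed by their per-gene mean.
#' Values are taken as-is — declared log-scale by default. For raw-scale
#' input, `log2Offset` applies `log2(x + offset)` at load.
#'
#' @param path path to the TSV file.
#' @param dropIncomplete drop rows containing missing values (default TRUE;
#'   with FALSE, any missing value is an error).
#' @param logScale declare the (possibly transformed) values log-scale.
#' @param log2Offset if non-NULL, apply `log2(x + log2Offset)` to the raw
#'   values.
#' @return An [ExpressionMatrix-class]; dropped-row count available via the
#'   `nDropped` slot.
#' @export
readExpression <- function(path, dropIncomplete = TRUE, logScale = TRUE,
                           log2Offset = NULL) {
    lines <- readLines(path)
    if (!length(lines))
        stop("expression file is empty: ", path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 3L)
        stop("malformed expression header (need >= 2 sample columns): line 1")
    samples <- header[-1L]
    if (anyDuplicated(samples))
        stop("duplicate sample ids in header")
    body <- strsplit(lines[-1L], "\t", fixed = TRUE)
    nfield <- lengths(body)
    bad <- which(nfield != length(header))
    if (length(bad))
        stop("row ", bad[1L] + 1L, " has ", nfield[bad[1L]],
             " fields, expected ", length(header))
    genes <- vapply(body, `[[`, "", 1L)
    vals <- suppressWarnings(
        vapply(body, function(f) as.numeric(f[-1L]),
               numeric(length(samples))))
    vals <- matrix(vals, ncol = length(samples), byrow = TRUE,
                   dimnames = list(NULL, samples))
    ## distinguish true "NA" tokens (missing) from non-numeric garbage
    raw <- matrix(vapply(body, function(f) f[-1L],
                         character(length(samples))),
                  ncol = length(samples), byrow = TRUE)
    garbage <- is.na(vals) & !(toupper(raw) %in% c("NA", "NAN", ""))
    if (any(garbage)) {
        idx <- which(garbage, arr.ind = TRUE)[1L, ]
        stop("non-numeric value '", raw[garbage][1L], "' at row ",
             idx[1L] + 1L, " (gene ", genes[idx[1L]], "), column ",
             samples[idx[2L]])
    }
    incomplete <- rowSums(is.na(vals)) > 0L
    if (any(incomplete) && !dropIncomplete)
        stop(sum(incomplete), " rows contain missing values ",
             "(set dropIncomplete = TRUE to drop them)")
    nDropped <- sum(incomplete)
    vals <- vals[!incomplete, , drop = FALSE]
    genes <- genes[!incomplete]
    if (anyDuplicated(genes)) {
        vals <- rowsum(vals, genes, reorder = FALSE) /
            as.vector(table(factor(genes, levels = unique(genes))))
        genes <- unique(genes)
    }
    rownames(vals) <- genes
    if (!is.null(log2Offset)) {
        vals <- log2(vals + log2Offset)
        logScale <- TRUE
    }
    ExpressionMatrix(vals, logScale = logScale, nDropped = nDropped)
}

#' Write an ExpressionMatrix as TSV
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path; a `.meta.json` sidecar is written alongside.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
    v <- exprValues(x)
    df <- data.frame(gene = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeSidecar(path, "expression_tsv",
                 list(n_genes = nrow(v), n_samples = ncol(v),
                      log_scale = x@logScale))
}

#' Read gene sets in GMT format
#'
#' One set per line: `name TAB description TAB gene TAB gene ...`. Genes
#' repeated within a line are de-duplicated with a warning.
#'
#' @param path path to the GMT file.
#' @return A [GeneSetList-class]; an empty file yields an empty collection.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(GeneSetList(stats::setNames(list(), character())))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 3L)
    if (length(short))
        stop("GMT line ", short[1L], " has fewer than 3 fields")
    nm <- vapply(fields, `[[`, "", 1L)
    desc <- vapply(fields, `[[`, "", 2L)
    sets <- lapply(fields, function(f) f[-(1:2)])
    nDup <- sum(vapply(sets, function(g) length(g) - length(unique(g)), 1L))
    if (nDup > 0L)
        warning(nDup, " duplicate gene entries removed across sets")
    sets <- lapply(sets, unique)
    GeneSetList(stats::setNames(sets, nm), stats::setNames(desc, nm))
}

#' Write a GeneSetList in GMT format
#'
#' @param x a [GeneSetList-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(x, path) {
    lines <- vapply(seq_along(x@sets), function(i) {
        paste(c(names(x@sets)[i], x@descriptions[i], x@sets[[i]]),
              collapse = "\t")
    }, "")
    writeLines(lines, path)
    writeSidecar(path, "gmt", list(n_sets = length(x@sets)))
}

mafRequired <- c(sample = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
                 class = "Variant_Classification", ref = "t_ref_count",
                 alt = "t_alt_count")

#' Read somatic mutations from a MAF file
#'
#' Requires the standard MAF columns `Tumor_Sample_Barcode`, `Hugo_Symbol`,
#' `Variant_Classification`, `t_ref_count` and `t_alt_count`; extra columns
#' are ignored and `#` comment lines skipped. Records with zero total read
#' depth are retained but flagged VAF-undefined.
#'
#' @param path path to the MAF file.
#' @return A [MutationTable-class].
#' @export
readMAF <- function(path) {
    df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(mafRequired, names(df))
    if (length(missing))
        stop("MAF is missing required column(s): ",
             paste(missing, collapse = ", "),
             "; found: ", paste(names(df), collapse = ", "))
    MutationTable(sample_id = df[[mafRequired[["sample"]]]],
                  gene_symbol = df[[mafRequired[["gene"]]]],
                  variant_class = df[[mafRequired[["class"]]]],
                  ref_count = df[[mafRequired[["ref"]]]],
                  alt_count = df[[mafRequired[["alt"]]]])
}

#' Write a MutationTable as a MAF-style TSV
#'
#' @param x a [MutationTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMAF <- function(x, path) {
    r <- mutationRecords(x)
    out <- data.frame(Hugo_Symbol = r$gene_symbol,
                      Tumor_Sample_Barcode = r$sample_id,
                      Variant_Classification = r$variant_class,
                      t_ref_count = r$ref_count,
                      t_alt_count = r$alt_count)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeSidecar(path, "maf", list(n_records = nrow(r)))
}

#' Read a thresholded copy-number call table
#'
#' GISTIC-style layout: first column the feature id (gene symbol or
#' chromosome arm), remaining columns integer calls in \{-2,-1,0,1,2\} per
#' sample.
#'
#' @param path path to the TSV file.
#' @param level `"gene"` or `"arm"`.
#' @return A [CopyNumberTable-class].
#' @export
readCopyNumber <- function(path, level = c("gene", "arm")) {
    level <- match.arg(level)
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    if (anyNA(suppressWarnings(as.integer(m))))
        stop("non-integer copy-number call in ", path)
    CopyNumberTable(m, level = level)
}

#' Write a CopyNumberTable as TSV
#'
#' @param x a [CopyNumberTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCopyNumber <- function(x, path) {
    m <- copyNumberCalls(x)
    df <- data.frame(feature = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeSidecar(path, "copy_number_tsv", list(level = x@level))
}

#' Read a clinical annotation table
#'
#' Expects columns `sample_id`, `survival_time`, `event_status`, `grade`,
#' `idh_status`, `histology` (missing values allowed; excluded per analysis,
#' never imputed).
#'
#' @param path path to the TSV file.
#' @param timeUnit declared unit of the survival times.
#' @return A [ClinicalTable-class].
#' @export
readClinical <- function(path, timeUnit = "months") {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE,
                            na.strings = c("NA", ""))
    need <- c("sample_id", "survival_time", "event_status", "grade",
              "idh_status", "histology")
    missing <- setdiff(need, names(df))
    if (length(missing))
        stop("clinical table missing column(s): ",
             paste(missing, collapse = ", "))
    df$sample_id <- as.character(df$sample_id)
    ClinicalTable(df[, need], timeUnit = timeUnit)
}

#' Write a ClinicalTable as TSV
#'
#' @param x a [ClinicalTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(x, path) {
    utils::write.table(clinicalData(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeSidecar(path, "clinical_tsv", list(time_unit = x@timeUnit))
}
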