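#' Construct a DescriptorSet
#'
#' @param values numeric samples-by-descriptors matrix (N x D), all finite.
#' @param labels class label per sample (factor or coercible); at least two
#'   distinct classes.
#' @param sampleIds optional sample identifiers (default `sample_1` ...).
#' @param descriptorNames optional descriptor names (default `desc_1` ...).
#' @param metadata optional named list stored in the object metadata.
#'
#' @return A \linkS4class{DescriptorSet}.
#' @examples
#' x <- DescriptorSet(matrix(rnorm(40), 10, 4),
#'                    labels = rep(c("a", "b"), each = 5))
#' dim(descriptorMatrix(x))
#' table(classLabels(x))
#' @export
DescriptorSet <- function(values, labels, sampleIds = NULL,
                          descriptorNames = NULL, metadata = list()) {
    values <- as.matrix(values)
    if (!is.numeric(values))
        stop("'values' must be a numeric matrix")
    n <- nrow(values)
    if (length(labels) != n)
        stop("'labels' must have one entry per sample (row)")
    if (is.null(sampleIds))
        sampleIds <- if (!is.null(rownames(values))) rownames(values)
                     else sprintf("sample_%d", seq_len(n))
    if (anyDuplicated(sampleIds))
        stop("'sampleIds' must be unique")
    if (is.null(descriptorNames))
        descriptorNames <- if (!is.null(colnames(values))) colnames(values)
                           else sprintf("desc_%d", seq_len(ncol(values)))
    dimnames(values) <- list(sampleIds, descriptorNames)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(descriptors = t(values)),
        colData = S4Vectors::DataFrame(label = factor(labels),
                                       row.names = sampleIds)
    )
    S4Vectors::metadata(se) <- metadata
    new("DescriptorSet", se)
}

#' @rdname descriptorMatrix
#' @export
setGeneric("descriptorMatrix", function(x) standardGeneric("descriptorMatrix"))

#' Accessors for DescriptorSet
#'
#' `descriptorMatrix()` returns the samples-by-descriptors (N x D) matrix;
#' `classLabels()` the per-sample class factor; `sampleIds()` the sample
#' identifiers; `descriptorNames()` the descriptor (column) names.
#'
#' @param x a \linkS4class{DescriptorSet}.
#' @return See description.
#' @export
setMethod("descriptorMatrix", "DescriptorSet", function(x) {
    t(SummarizedExperiment::assay(x, "descriptors"))
})

#' @rdname descriptorMatrix
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname descriptorMatrix
#' @export
setMethod("classLabels", "DescriptorSet", function(x) {
    droplevels(factor(SummarizedExperiment::colData(x)$label))
})

#' @rdname descriptorMatrix
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname descriptorMatrix
#' @export
setMethod("sampleIds", "DescriptorSet", function(x) colnames(x))

#' @rdname descriptorMatrix
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' @rdname descriptorMatrix
#' @export
setMethod("descriptorNames", "DescriptorSet", function(x) rownames(x))

setMethod("show", "DescriptorSet", function(object) {
    lab <- classLabels(object)
    cat("DescriptorSet:", ncol(object), "samples x", nrow(object),
        "descriptors\n")
    cat("classes:",
        paste(sprintf("%s (%d)", levels(lab), tabulate(lab)), collapse = ", "),
        "\n")
    conv <- S4Vectors::metadata(object)$standardization
    if (!is.null(conv))
        cat("standardized: z-scores,", conv, "convention\n")
})

# subset rows (samples) of a DescriptorSet by index, keeping metadata
subsetSamples <- function(x, idx) {
    out <- x[, idx]
    methods::validObject(out)
    out
}

#' Write / read a DescriptorSet as CSV
#'
#' The on-disk layout is one header row, a `sample_id` column, a `label`
#' column, then one column per descriptor.  Values are written with 17
#' significant digits so that write/read round-trips are lossless for
#' doubles.
#'
#' @param x a \linkS4class{DescriptorSet}.
#' @param path file path.
#' @return `writeDescriptorCSV()` returns `path` invisibly;
#'   `readDescriptorCSV()` returns a \linkS4class{DescriptorSet}.
#' @export
writeDescriptorCSV <- function(x, path) {
    mat <- descriptorMatrix(x)
    df <- data.frame(sample_id = sampleIds(x),
                     label = as.character(classLabels(x)),
                     check.names = FALSE, stringsAsFactors = FALSE)
    num <- as.data.frame(apply(mat, 2, function(v) sprintf("%.17g", v)),
                         stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(cbind(df, num), path, sep = ",", quote = TRUE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeDescriptorCSV
#' @export
readDescriptorCSV <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "label") %in% colnames(df)))
        stop("descriptor CSV must contain 'sample_id' and 'label' columns")
    descCols <- setdiff(colnames(df), c("sample_id", "label"))
    mat <- as.matrix(df[, descCols, drop = FALSE])
    storage.mode(mat) <- "double"
    DescriptorSet(mat, labels = df$label, sampleIds = df$sample_id,
                  descriptorNames = descCols)
}
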