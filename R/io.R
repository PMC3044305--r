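# atomic file write: produce into a temp file in the target directory,
# then rename, so interrupted runs never leave partial artifacts
writeAtomic <- function(path, writer) {
    tmp <- tempfile(basename(path), dirname(path))
    ok <- FALSE
    on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
    writer(tmp)
    if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
    ok <- TRUE
    invisible(path)
}

#' Write a similarity or distance matrix as TSV
#'
#' The first line is a `#type=similarity` / `#type=distance` marker so
#' readers cannot silently misinterpret the scale; then a header row of
#' ids and one labelled row per sequence.
#'
#' @param mat [SimilarityMatrix-class] or named square matrix.
#' @param path output file.
#' @param type `"similarity"` or `"distance"`.
#' @return invisibly, the path.
#' @export
writeMatrixTSV <- function(mat, path, type = c("similarity", "distance")) {
    type <- match.arg(type)
    v <- if (is(mat, "SimilarityMatrix")) similarityValues(mat) else as.matrix(mat)
    writeAtomic(path, function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        writeLines(paste0("#type=", type), con)
        writeLines(paste(c("id", colnames(v)), collapse = "\t"), con)
        for (i in seq_len(nrow(v)))
            writeLines(paste(c(rownames(v)[i],
                               format(v[i, ], digits = 15, trim = TRUE)),
                             collapse = "\t"), con)
    })
}

#' Read a matrix TSV written by [writeMatrixTSV()]
#'
#' @param path input file.
#' @return list with `values` (named matrix) and `type`.
#' @export
readMatrixTSV <- function(path) {
    first <- readLines(path, n = 1)
    if (!grepl("^#type=(similarity|distance)$", first))
        stop("matrix file lacks the #type=similarity|distance header: ", path)
    type <- sub("^#type=", "", first)
    df <- read.table(path, sep = "\t", header = TRUE, skip = 1,
                     row.names = 1, check.names = FALSE)
    v <- as.matrix(df)
    colnames(v) <- colnames(df)
    if (!identical(rownames(v), colnames(v)))
        stop("matrix row and column ids differ: ", path)
    list(values = v, type = type)
}

#' Write a square distance matrix in PHYLIP format
#'
#' @param mat named square numeric matrix.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writePhylipMatrix <- function(mat, path) {
    v <- as.matrix(mat)
    writeAtomic(path, function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        writeLines(format(nrow(v)), con)
        for (i in seq_len(nrow(v)))
            writeLines(paste(c(sprintf("%-10s", rownames(v)[i]),
                               format(v[i, ], digits = 10, trim = TRUE)),
                             collapse = " "), con)
    })
}

#' Write a flat clustering as TSV (columns id, cluster)
#'
#' @param clustering named vector (id -> cluster label).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeClusteringTSV <- function(clustering, path) {
    df <- data.frame(id = names(clustering),
                     cluster = as.vector(clustering))
    writeAtomic(path, function(tmp)
        write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}

#' Read a reference clustering TSV (columns id, cluster)
#'
#' @param path input file; header optional (detected by an `id` first
#'   field).
#' @return named character vector id -> cluster label.
#' @export
readReferenceTSV <- function(path) {
    first <- strsplit(readLines(path, n = 1), "\t")[[1]]
    hasHeader <- identical(tolower(first[1]), "id")
    df <- read.table(path, sep = "\t", header = hasHeader,
                     colClasses = "character")
    if (ncol(df) < 2) stop("reference TSV needs two columns (id, cluster): ", path)
    if (anyDuplicated(df[[1]])) stop("duplicate ids in reference TSV: ", path)
    structure(df[[2]], names = df[[1]])
}

#' Write ROC points as CSV (columns fpr, tpr)
#'
#' @param points data.frame from [rocCurve()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRocCSV <- function(points, path) {
    writeAtomic(path, function(tmp)
        write.table(points, tmp, sep = ",", quote = FALSE, row.names = FALSE))
}

#' Write a Newick tree file
#'
#' @param tree a [ClusterTree-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeNewickFile <- function(tree, path) {
    writeAtomic(path, function(tmp) writeLines(toNewick(tree), tmp))
}
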