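## Reading/writing counts and annotations, subtype merging, the
## stratified half split and the rare-type rule.

.countsOf <- function(x) {
    if (methods::is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts")
    else x
}

.checkCounts <- function(m) {
    v <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
    if (any(v < 0)) stop("counts must be nonnegative")
    if (any(v != floor(v))) stop("counts must be integral")
    if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers")
    if (anyDuplicated(colnames(m))) stop("duplicate cell identifiers")
    invisible(m)
}

#' Read a gene-by-cell count matrix
#'
#' Supports the 10x-style MatrixMarket triplet (a directory holding
#' `matrix.mtx`, `genes.tsv`, `barcodes.tsv`) and dense delimited text
#' (first column gene identifiers, header row cell identifiers).
#' Orientation is normalized to genes x cells.
#'
#' @param path directory (`format = "mtx"`) or file (`format = "csv"`).
#' @param format `"mtx"` or `"csv"` (the latter also reads TSV; the
#'   separator is sniffed from the extension).
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay.
#' @examples
#' sce <- presetScenario("small", seed = 1)
#' d <- tempfile(); writeCounts(sce, d, format = "mtx")
#' sce2 <- readCounts(d, format = "mtx")
#' identical(dim(sce2), dim(sce))
#' @export
readCounts <- function(path, format = c("mtx", "csv")) {
    format <- match.arg(format)
    if (format == "mtx") {
        mtx <- file.path(path, "matrix.mtx")
        gf <- file.path(path, "genes.tsv")
        bf <- file.path(path, "barcodes.tsv")
        for (f in c(mtx, gf, bf))
            if (!file.exists(f)) stop("missing file: ", f)
        m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
        genes <- read.delim(gf, header = FALSE)[[1L]]
        cells <- read.delim(bf, header = FALSE)[[1L]]
        if (nrow(m) != length(genes) || ncol(m) != length(cells))
            stop("matrix dimensions do not match genes.tsv/barcodes.tsv")
        dimnames(m) <- list(genes, cells)
    } else {
        if (!file.exists(path)) stop("missing file: ", path)
        sep <- if (grepl("\\.csv$", path)) "," else "\t"
        d <- read.delim(path, sep = sep, check.names = FALSE, row.names = 1L)
        m <- methods::as(Matrix::Matrix(as.matrix(d), sparse = TRUE), "CsparseMatrix")
    }
    .checkCounts(m)
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write a count matrix (MatrixMarket triplet or dense delimited)
#'
#' The inverse of [readCounts()]; also writes the cell annotation as
#' `annotation.tsv` (columns `cell_id`, `subtype`, `major_type`, `age`)
#' when the input carries one.
#'
#' @param x a SingleCellExperiment or genes x cells matrix.
#' @param path output directory (mtx) or file (csv).
#' @param format `"mtx"` or `"csv"`.
#' @return the path, invisibly.
#' @export
writeCounts <- function(x, path, format = c("mtx", "csv")) {
    format <- match.arg(format)
    m <- .countsOf(x)
    if (format == "mtx") {
        dir.create(path, showWarnings = FALSE, recursive = TRUE)
        Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                        file.path(path, "matrix.mtx"))
        writeLines(rownames(m), file.path(path, "genes.tsv"))
        writeLines(colnames(m), file.path(path, "barcodes.tsv"))
        if (methods::is(x, "SummarizedExperiment") &&
            all(c("subtype", "major_type", "age") %in%
                colnames(SummarizedExperiment::colData(x)))) {
            ann <- as.data.frame(SummarizedExperiment::colData(x))
            write.table(ann[, c("cell_id", "subtype", "major_type", "age")],
                        file.path(path, "annotation.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
        }
    } else {
        sep <- if (grepl("\\.csv$", path)) "," else "\t"
        d <- as.matrix(m)
        write.table(data.frame(gene = rownames(d), d, check.names = FALSE),
                    path, sep = sep, quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

.annOf <- function(x) {
    if (methods::is(x, "SummarizedExperiment"))
        as.data.frame(SummarizedExperiment::colData(x))
    else as.data.frame(x)
}

#' Merge cell subtypes into major types
#'
#' Relabels every subtype by its major type (the analysis merges e.g.
#' the B- and T-cell subtypes into one B and one T class).  The mapping
#' must cover every subtype present.
#'
#' @param ann annotation data.frame (or SingleCellExperiment colData)
#'   with a `subtype` column.
#' @param mapping named character vector, `subtype -> major type`.
#' @return the annotation with `major_type` (re)assigned; cell count
#'   unchanged.
#' @examples
#' ann <- data.frame(cell_id = c("c1", "c2"),
#'                   subtype = c("Naive CD4 T", "Naive CD8 T"))
#' mergeSubtypes(ann, c("Naive CD4 T" = "T", "Naive CD8 T" = "T"))$major_type
#' @export
mergeSubtypes <- function(ann, mapping) {
    ann <- .annOf(ann)
    missing <- setdiff(unique(as.character(ann$subtype)), names(mapping))
    if (length(missing))
        stop("unmapped subtypes: ", paste(missing, collapse = ", "))
    ann$major_type <- unname(mapping[as.character(ann$subtype)])
    ann
}

#' Stratified half split into training and testing cells
#'
#' Within each major type, `floor(fraction * n)` cells are drawn at
#' random into the training set and the remainder into the testing set,
#' so the training set keeps a balanced representation of every cell
#' type (including rare ones).  The floor goes to training on odd
#' counts.
#'
#' @param ann annotation with `cell_id` and `major_type`.
#' @param fraction training fraction in (0, 1); default the half split.
#' @param seed integer seed; the assignment is deterministic given it.
#' @return list with `train`, `test` (disjoint cell-id vectors whose
#'   union is all cells), `fraction` and `seed`.
#' @examples
#' ann <- data.frame(cell_id = sprintf("c%02d", 1:41),
#'                   major_type = rep(c("A", "B"), c(20, 21)))
#' sp <- stratifiedSplit(ann, seed = 1)
#' lengths(sp[c("train", "test")])
#' @export
stratifiedSplit <- function(ann, fraction = 0.5, seed = 1L) {
    ann <- .annOf(ann)
    if (nrow(ann) == 0L) stop("empty annotation")
    if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
    set.seed(seed)
    train <- character()
    for (ty in unique(as.character(ann$major_type))) {
        ids <- ann$cell_id[ann$major_type == ty]
        nTrain <- floor(fraction * length(ids))
        train <- c(train, sample(ids, nTrain))
    }
    list(train = train,
         test = setdiff(ann$cell_id, train),
         fraction = fraction, seed = as.integer(seed))
}

#' Flag rare cell types
#'
#' A cell type is rare if its training set holds fewer than `minYoung`
#' young cells or fewer than `minOld` old cells (strict inequality; 30
#' of each is not rare).
#'
#' @param ann annotation with `cell_id`, `major_type`, `age`.
#' @param split a [stratifiedSplit()] result.
#' @param minYoung,minOld rarity thresholds.
#' @return character vector of rare major types.
#' @examples
#' sce <- presetScenario("small", seed = 1)
#' sp <- stratifiedSplit(colData(sce), seed = 2)
#' flagRareTypes(colData(sce), sp)
#' @export
flagRareTypes <- function(ann, split, minYoung = 30L, minOld = 30L) {
    ann <- .annOf(ann)
    tr <- ann[ann$cell_id %in% split$train, ]
    out <- character()
    for (ty in unique(as.character(ann$major_type))) {
        a <- tr[tr$major_type == ty, ]
        if (sum(a$age == "young") < minYoung || sum(a$age == "old") < minOld)
            out <- c(out, ty)
    }
    out
}

#' Drop genes below a total-count threshold
#'
#' Removes genes whose total count over the reference cells (typically
#' the training set: the fitted vocabulary must be shared with fold-in
#' cells, so test cells never enlarge it) is below `minTotal`.
#' Zero-count genes make topic-gene frequency columns unidentifiable,
#' hence the default of 1.
#'
#' @param x SingleCellExperiment or genes x cells matrix.
#' @param minTotal minimum total count to keep a gene.
#' @param cells optional cell ids over which totals are computed
#'   (default: all cells).
#' @return `x` restricted to the kept genes; the number removed is
#'   reported via a message.
#' @examples
#' m <- matrix(c(1, 0, 2, 0, 0, 0), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:2)))
#' dim(filterGenesMinCount(m))
#' @export
filterGenesMinCount <- function(x, minTotal = 1L, cells = NULL) {
    m <- .countsOf(x)
    ref <- if (is.null(cells)) m else m[, colnames(m) %in% cells, drop = FALSE]
    keep <- Matrix::rowSums(ref) >= minTotal
    if (!any(keep)) stop("all genes removed; lower minTotal")
    if (any(!keep))
        message(sum(!keep), " gene(s) below total count ", minTotal, " removed")
    x[keep, , drop = FALSE]
}
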