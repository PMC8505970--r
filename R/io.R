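## Readers/writers for the plain-text interchange formats: expression TSV,
## phenotype TSV, gene-weight TSV and a minimal GEO series-matrix dialect.
## All readers validate and refuse malformed input rather than repairing it.

.readTSVTable <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(first))
    stop("empty file or missing header: ", path, call. = FALSE)
  read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
             comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a tab-separated file with a header row. In the canonical
#' orientation (`"genes-in-rows"`) the first column holds gene symbols and
#' the header the sample ids; `"samples-in-rows"` reads the transpose. The
#' in-memory layout is always genes x samples. Duplicate gene symbols are
#' rejected: collapsing probe-level duplicates is a deliberate analysis step
#' ([collapseDuplicates()]), never an import side effect.
#'
#' @param path path to the TSV file.
#' @param orientation `"genes-in-rows"` (default) or `"samples-in-rows"`.
#' @return a [UCCohort-class] without sample annotations.
#' @seealso [writeExpressionTSV()], [readPhenotypeTSV()]
#' @export
readExpressionTSV <- function(path,
                              orientation = c("genes-in-rows",
                                              "samples-in-rows")) {
  orientation <- match.arg(orientation)
  df <- .readTSVTable(path)
  if (ncol(df) < 2L)
    stop("expression TSV needs an id column plus at least one value column: ",
         path, call. = FALSE)
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  nonNum <- !vapply(vals, is.numeric, logical(1L))
  if (any(nonNum))
    stop("non-numeric expression values in column(s): ",
         paste(colnames(vals)[nonNum], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "samples-in-rows")
    m <- t(m)
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene ids (collapse explicitly with collapseDuplicates): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(m)))
    stop("missing or non-finite expression values in ", path, call. = FALSE)
  UCCohort(m)
}

#' Write an expression matrix to TSV
#'
#' Writes genes in rows, first column `gene`, header = sample ids; plain
#' decimal notation, UTF-8, tab-separated. Round-trips with
#' [readExpressionTSV()] to machine precision.
#'
#' @param x a [UCCohort-class] or genes x samples numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionTSV <- function(x, path) {
  m <- if (is(x, "UCCohort")) expressionMatrix(x) else x
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' Columns `sample_id`, `response` (`"responder"`/`"non_responder"`) and
#' `batch`, tab-separated with a header.
#'
#' @param path path to the TSV file.
#' @return data.frame with character columns `sample_id`, `response`, `batch`.
#' @export
readPhenotypeTSV <- function(path) {
  df <- .readTSVTable(path)
  need <- c("sample_id", "response", "batch")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("phenotype TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[, need]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in phenotype table: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$response), c("responder", "non_responder"))
  if (length(bad))
    stop("unknown response label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a phenotype table to TSV
#' @param pheno data.frame with `sample_id`, `response`, `batch`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypeTSV <- function(pheno, path) {
  write.table(pheno[, c("sample_id", "response", "batch")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Attach phenotype annotations to a cohort
#'
#' Matches the phenotype rows to the cohort's samples by `sample_id`;
#' every sample must have exactly one phenotype row.
#'
#' @param cohort a [UCCohort-class].
#' @param pheno data.frame from [readPhenotypeTSV()].
#' @return the annotated [UCCohort-class].
#' @export
attachPhenotype <- function(cohort, pheno) {
  ids <- colnames(cohort)
  missing <- setdiff(ids, pheno$sample_id)
  if (length(missing))
    stop("no phenotype row for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ph <- pheno[match(ids, pheno$sample_id), ]
  UCCohort(expressionMatrix(cohort), response = ph$response, batch = ph$batch)
}

#' Read a GEO-style series-matrix text file
#'
#' Minimal reader for the series-matrix dialect: `!Sample_*` annotation lines
#' plus the expression block between `!series_matrix_table_begin` and
#' `!series_matrix_table_end` (first column gene/probe ids, header sample
#' ids, values possibly double-quoted). Intended for small local files; no
#' network access.
#'
#' @param path path to the series-matrix text file.
#' @return list with elements `cohort` (a [UCCohort-class]) and
#'   `annotations` (named list mapping each `!Sample_*` key to its values).
#' @export
readSeriesMatrix <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin)
    stop("missing series-matrix table delimiters in ", path, call. = FALSE)
  ann <- list()
  for (ln in grep("^!Sample_", lines, value = TRUE)) {
    fields <- gsub('^"|"$', "", strsplit(ln, "\t", fixed = TRUE)[[1L]])
    ann[[sub("^!", "", fields[1L])]] <- fields[-1L]
  }
  block <- lines[(begin + 1L):(end - 1L)]
  con <- textConnection(block)
  on.exit(close(con))
  df <- read.delim(con, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- gsub('^"|"$', "", colnames(df))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric values in series-matrix table of ", path, call. = FALSE)
  rownames(m) <- gsub('^"|"$', "", as.character(df[[1L]]))
  list(cohort = UCCohort(m), annotations = ann)
}

.asGeneWeightTable <- function(gene, weight, direction) {
  new("GeneWeightTable", gene = as.character(gene),
      weight = as.numeric(weight), direction = as.character(direction))
}

#' Construct a gene weight table
#' @param gene character gene symbols (unique).
#' @param weight numeric weights, finite.
#' @param direction `"up"`/`"down"` per gene, relative to responders.
#' @return a [GeneWeightTable-class].
#' @export
GeneWeightTable <- function(gene, weight, direction) {
  .asGeneWeightTable(gene, weight, direction)
}

#' Read a gene weight table from TSV
#'
#' Expects columns `gene` and `weight`, optionally `direction`; when the
#' direction column is absent every gene defaults to `"down"` (the
#' predominant orientation of the signature: lower in responders).
#'
#' @param path path to the TSV file.
#' @return a [GeneWeightTable-class].
#' @export
readGeneWeights <- function(path) {
  df <- .readTSVTable(path)
  need <- c("gene", "weight")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("weight TSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(df$weight))
    stop("non-numeric weight values in ", path, call. = FALSE)
  dir <- if ("direction" %in% colnames(df)) df$direction
         else rep("down", nrow(df))
  .asGeneWeightTable(df$gene, df$weight, dir)
}

#' Write a gene weight table to TSV
#' @param x a [GeneWeightTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneWeights <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Published training Gene Weights of the 30-gene signature
#'
#' Loads the packaged reference table of Gene Weights obtained on the
#' original training cohorts (GSE16879 + GSE12251): 30 genes, all-positive
#' weights, with C10orf99 and ADH1C expressed higher in responders and the
#' other 28 genes higher in non-responders.
#'
#' @return a [GeneWeightTable-class] with 30 entries.
#' @examples
#' w <- trainingGeneWeights()
#' geneWeights(w)[["IL6"]]
#' @export
trainingGeneWeights <- function() {
  path <- system.file("extdata", "training_gene_weights.tsv",
                      package = "molPS", mustWork = TRUE)
  readGeneWeights(path)
}
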