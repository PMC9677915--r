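## Readers/writers for the tabular formats used throughout the package.
## All tables are UTF-8, tab-separated, decimal point ".", scientific
## notation accepted. Gene identifiers are HGNC-style symbols, uppercased
## and whitespace-trimmed on load; missing metadata values may be encoded
## as "" or "NA"; missing expression values are an error.

.normSymbols <- function(x) toupper(trimws(as.character(x)))

#' Construct an expression matrix container
#'
#' Wraps a dense gene x sample matrix in a
#' \link[SummarizedExperiment]{SummarizedExperiment} whose single assay is
#' named after the unit (\code{"counts"} or \code{"log2"}). Validates that
#' identifiers are unique, values are complete and, for counts, non-negative.
#'
#' @param values numeric matrix with gene-symbol rownames and sample-id
#'   colnames.
#' @param unit \code{"counts"} for raw (non-negative) counts or
#'   \code{"log2"} for log2-scale expression.
#' @param colData optional per-sample metadata (data.frame or DataFrame)
#'   whose rownames match the sample ids.
#' @return A \code{SummarizedExperiment} with \code{metadata(x)$unit} set.
#' @export
#' @examples
#' m <- matrix(rpois(6, 10), 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' se <- ExpressionMatrix(m, unit = "counts")
ExpressionMatrix <- function(values, unit = c("counts", "log2"),
                             colData = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames")
  rownames(values) <- .normSymbols(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("expression values must be complete and numeric")
  if (unit == "counts" && any(values < 0))
    stop("counts must be non-negative")
  assays <- setNames(list(values), unit)
  if (is.null(colData)) {
    se <- SummarizedExperiment::SummarizedExperiment(assays = assays)
  } else {
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = assays, colData = S4Vectors::DataFrame(colData))
  }
  S4Vectors::metadata(se)$unit <- unit
  se
}

#' Expression unit and values of an expression container
#'
#' @param x a \code{SummarizedExperiment} built by [ExpressionMatrix()] (or
#'   any SE whose first assay is the expression matrix), or a plain matrix.
#' @return \code{exprUnit}: the unit tag (\code{NA} for untagged matrices);
#'   \code{exprValues}: the numeric gene x sample matrix.
#' @export
exprUnit <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    u <- S4Vectors::metadata(x)$unit
    if (!is.null(u)) return(u)
    an <- SummarizedExperiment::assayNames(x)
    if (!is.null(an) && an[1] %in% c("counts", "log2")) return(an[1])
    return(NA_character_)
  }
  u <- attr(x, "unit")
  if (is.null(u)) NA_character_ else u
}

#' @rdname exprUnit
#' @export
exprValues <- function(x) {
  if (is(x, "SummarizedExperiment"))
    return(as.matrix(SummarizedExperiment::assay(x, 1)))
  as.matrix(x)
}

.checkUnit <- function(x, expected) {
  u <- exprUnit(x)
  if (!is.na(u) && u != expected)
    stop("expression input has unit '", u, "' but '", expected,
         "' is required")
  invisible(TRUE)
}

#' Read a gene x sample expression TSV
#'
#' Reads a tab-separated expression table whose header row holds sample ids
#' and whose first column holds gene symbols. Symbols are uppercased;
#' duplicate gene symbols are collapsed by keeping the row with the highest
#' mean (reported via a message); any non-numeric or missing cell is an
#' error naming the offending gene and sample.
#'
#' @param path file path to the TSV.
#' @param unit unit of the stored values, \code{"counts"} or \code{"log2"}.
#' @return A \code{SummarizedExperiment}; see [ExpressionMatrix()].
#' @export
readExpressionMatrix <- function(path, unit = c("counts", "log2")) {
  unit <- match.arg(unit)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("format error: expected a header row with at least one sample id")
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    stop("format error: duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- .normSymbols(raw[[1]])
  vals <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(NULL, samples))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1, ]
    stop("parse error: non-numeric or missing value at gene '",
         genes[b[1]], "', sample '", samples[b[2]], "' (cell '",
         raw[b[1], b[2] + 1L], "')")
  }
  if (anyDuplicated(genes)) {
    means <- rowMeans(vals)
    ord <- order(genes, -means)
    keep <- ord[!duplicated(genes[ord])]
    dropped <- sum(duplicated(genes))
    message("collapsed ", dropped, " duplicate gene row(s), keeping the ",
            "highest-mean row per symbol")
    keep <- sort(keep)
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  rownames(vals) <- genes
  ExpressionMatrix(vals, unit = unit)
}

#' Write an expression matrix to TSV
#'
#' @param x expression container or matrix.
#' @param path output path.
#' @param geneCol name of the first (gene) column.
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, geneCol = "gene") {
  m <- exprValues(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- geneCol
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read clinical sample metadata
#'
#' Reads a clinical TSV with at least \code{sample_id} and
#' \code{tissue_class} columns (values \code{tumor}/\code{non_tumor});
#' recognised optional columns are \code{time_months}, \code{event},
#' \code{age_years}, \code{stage}, \code{sex}, \code{smoking_status} and
#' \code{cohort}. Empty strings and \code{"NA"} are read as missing;
#' \code{tissue_class} must be complete.
#'
#' @param path file path.
#' @return data.frame with one row per sample.
#' @export
readSampleMetadata <- function(path) {
  md <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  if (!all(c("sample_id", "tissue_class") %in% colnames(md)))
    stop("schema error: metadata requires 'sample_id' and 'tissue_class' columns")
  md[md == "" | md == "NA"] <- NA
  if (anyDuplicated(md$sample_id))
    stop("schema error: duplicate sample_id in metadata")
  if (anyNA(md$tissue_class))
    stop("schema error: tissue_class must be present for every sample")
  if (!all(md$tissue_class %in% c("tumor", "non_tumor")))
    stop("schema error: tissue_class must be 'tumor' or 'non_tumor'")
  for (num in intersect(c("time_months", "event", "age_years"), colnames(md)))
    md[[num]] <- as.numeric(md[[num]])
  rownames(md) <- md$sample_id
  md
}

#' Attach sample metadata to an expression container
#'
#' Joins metadata rows to the expression samples by id and stores them as
#' \code{colData}; expression samples without metadata are reported in a
#' warning and retained with missing metadata.
#'
#' @param se expression \code{SummarizedExperiment}.
#' @param metadata data.frame from [readSampleMetadata()].
#' @return The annotated \code{SummarizedExperiment}.
#' @export
attachMetadata <- function(se, metadata) {
  ids <- colnames(se)
  unmatched <- setdiff(ids, metadata$sample_id)
  if (length(unmatched))
    warning("no metadata for ", length(unmatched), " sample(s): ",
            paste(unmatched, collapse = ", "))
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(md) <- ids
  SummarizedExperiment::colData(se) <- S4Vectors::DataFrame(md)
  se
}

#' Read a GMT gene-set collection
#'
#' Each line: set name, description, then gene symbols (tab-separated).
#' Symbols are uppercased and trimmed; lines with fewer than three fields
#' are a format error.
#'
#' @param path file path.
#' @return Named list of character vectors; descriptions kept in
#'   \code{attr(,"description")}.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("format error: GMT line ", short[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop("format error: duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(.normSymbols(f[-c(1, 2)])))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(fields, `[[`, "", 2L), nm)
  sets
}

#' Read a matrisome annotation table
#'
#' TSV with columns \code{gene}, \code{division} (\code{core_matrisome} or
#' \code{matrisome_associated}) and \code{category} (collagens,
#' proteoglycans, ECM_glycoproteins, ECM_affiliated, ECM_regulators,
#' secreted_factors). Checks that each gene appears once and that the
#' category is consistent with the division (the three structural
#' categories belong to the core matrisome).
#'
#' @param path file path.
#' @return data.frame with uppercased gene symbols.
#' @export
readMatrisomeAnnotation <- function(path) {
  ann <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  need <- c("gene", "division", "category")
  if (!all(need %in% colnames(ann)))
    stop("schema error: annotation requires columns ",
         paste(need, collapse = ", "))
  ann$gene <- .normSymbols(ann$gene)
  if (anyDuplicated(ann$gene))
    stop("schema error: duplicated gene(s) in matrisome annotation")
  coreCats <- c("collagens", "proteoglycans", "ECM_glycoproteins")
  assocCats <- c("ECM_affiliated", "ECM_regulators", "secreted_factors")
  if (!all(ann$division %in% c("core_matrisome", "matrisome_associated")))
    stop("schema error: unknown matrisome division")
  if (!all(ann$category %in% c(coreCats, assocCats)))
    stop("schema error: unknown matrisome category")
  inconsistent <- (ann$category %in% coreCats) !=
    (ann$division == "core_matrisome")
  if (any(inconsistent))
    stop("schema error: category/division mismatch for ",
         paste(ann$gene[inconsistent], collapse = ", "))
  ann
}

#' Read a ligand-receptor pair table
#'
#' TSV with columns \code{ligand}, \code{receptor}, \code{receptor_class}
#' and \code{pathways} (semicolon-delimited). Pairs must be unique. When a
#' matrisome annotation is supplied, ligands are restricted to
#' core-matrisome genes (non-core pairs dropped with a message).
#'
#' @param path file path.
#' @param matrisome optional annotation from [readMatrisomeAnnotation()].
#' @return data.frame of pairs.
#' @export
readLigandReceptorPairs <- function(path, matrisome = NULL) {
  lr <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", quote = "")
  need <- c("ligand", "receptor", "receptor_class", "pathways")
  if (!all(need %in% colnames(lr)))
    stop("schema error: ligand-receptor table requires columns ",
         paste(need, collapse = ", "))
  lr$ligand <- .normSymbols(lr$ligand)
  lr$receptor <- .normSymbols(lr$receptor)
  key <- paste(lr$ligand, lr$receptor)
  if (anyDuplicated(key))
    stop("schema error: duplicated ligand-receptor pair(s)")
  if (!is.null(matrisome)) {
    core <- matrisome$gene[matrisome$division == "core_matrisome"]
    drop <- !(lr$ligand %in% core)
    if (any(drop)) {
      message("dropping ", sum(drop),
              " pair(s) whose ligand is not a core-matrisome gene")
      lr <- lr[!drop, , drop = FALSE]
    }
  }
  rownames(lr) <- NULL
  lr
}

#' Read a +/-1-weighted fibrosis gene signature
#'
#' TSV with columns \code{gene} and \code{weight}; weights must be +1 (gene
#' up in fibrotic lung) or -1 (down).
#'
#' @param path file path.
#' @return data.frame with columns gene, weight.
#' @export
readFibrosisSignature <- function(path) {
  sig <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    quote = "")
  if (!all(c("gene", "weight") %in% colnames(sig)))
    stop("schema error: fibrosis signature requires columns gene, weight")
  sig$gene <- .normSymbols(sig$gene)
  sig$weight <- as.numeric(sig$weight)
  if (anyDuplicated(sig$gene))
    stop("schema error: duplicated gene(s) in fibrosis signature")
  if (!all(sig$weight %in% c(-1, 1)))
    stop("schema error: fibrosis weights must be +1 or -1")
  sig
}

#' Write and read a risk signature table
#'
#' The on-disk form is a TSV with columns \code{gene}, \code{beta} and
#' \code{odds_ratio}.
#'
#' @param signature a [RiskSignature-class].
#' @param path file path.
#' @return \code{writeRiskSignature}: the path, invisibly;
#'   \code{readRiskSignature}: a [RiskSignature-class].
#' @export
writeRiskSignature <- function(signature, path) {
  df <- data.frame(gene = signature@genes, beta = unname(signature@beta),
                   odds_ratio = exp(unname(signature@beta)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRiskSignature
#' @export
readRiskSignature <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "")
  new("RiskSignature", genes = .normSymbols(df$gene),
      beta = setNames(as.numeric(df$beta), .normSymbols(df$gene)),
      provenance = list(source = path))
}

#' Write and read a z-scaling model
#'
#' Stores the per-gene means and SDs of a [ZScaledMatrix-class] so external
#' cohorts can be projected onto the same scale (TSV columns: gene, mean, sd).
#'
#' @param z a [ZScaledMatrix-class].
#' @param path file path.
#' @return \code{writeZScaleModel}: the path, invisibly;
#'   \code{readZScaleModel}: a [ZScaledMatrix-class] carrying only the
#'   scaling parameters (empty sample dimension).
#' @export
writeZScaleModel <- function(z, path) {
  df <- data.frame(gene = names(z@geneMeans), mean = unname(z@geneMeans),
                   sd = unname(z@geneSds))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeZScaleModel
#' @export
readZScaleModel <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "")
  g <- .normSymbols(df$gene)
  new("ZScaledMatrix",
      z = matrix(numeric(0), nrow = length(g), ncol = 0,
                 dimnames = list(g, character(0))),
      geneMeans = setNames(as.numeric(df$mean), g),
      geneSds = setNames(as.numeric(df$sd), g),
      droppedGenes = character(0), cohort = path)
}
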