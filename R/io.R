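# Input/output for the standard study artifacts: sample x OTU count table,
# taxonomy lineages, sample metadata and the OTU phylogeny, plus the two
# global filtering rules applied before any analysis (minimum-count OTU
# filter and rarefaction to a fixed depth).

#' Taxonomic ranks used throughout the package
#' @export
TAXONOMY_RANKS <- c(
  "kingdom", "phylum", "class", "order", "family", "genus", "species"
)

#' Labels treated as unknown ("microbial dark matter") at any rank
#'
#' A rank label matching one of these markers (case-insensitive, trimmed,
#' underscores equivalent to spaces), or a missing/empty label, marks the
#' taxon as unidentified at that rank.
#' @export
UNKNOWN_TAXON_MARKERS <- c(
  "unknown", "unassigned", "ambiguous taxa", "uncultured",
  "uncultured bacterium", "na"
)

#' Test whether taxonomy labels are unknown markers
#'
#' @param x character vector of rank labels.
#' @return logical vector, `TRUE` where the label is an unknown marker,
#'   empty, or `NA`.
#' @export
is_unknown_label <- function(x) {
  norm <- tolower(trimws(gsub("_", " ", as.character(x))))
  is.na(x) | norm == "" | norm %in% UNKNOWN_TAXON_MARKERS
}

validate_otu_counts <- function(counts) {
  if (!is.matrix(counts)) {
    stop("OTU table must be a matrix (samples x OTUs)", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("OTU table must carry sample ids (rows) and OTU ids (columns)",
      call. = FALSE
    )
  }
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_s) > 0) {
    stopf("duplicate sample id(s): %s", paste(dup_s, collapse = ", "))
  }
  dup_o <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_o) > 0) {
    stopf("duplicate OTU id(s): %s", paste(dup_o, collapse = ", "))
  }
  if (anyNA(counts)) stop("OTU table contains missing values", call. = FALSE)
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stopf(
      "negative count at sample '%s', OTU '%s'",
      rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]
    )
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("OTU table contains non-integer counts", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read a sample x OTU count table
#'
#' TSV dialect: tab-separated, UTF-8, no quoting; first column holds OTU
#' ids, header row holds sample ids (i.e. OTUs as file rows, the common
#' orientation). The returned matrix is always samples x OTUs. Set
#' `samples_as_rows = TRUE` only when the file is known to be transposed;
#' orientation is never guessed. BIOM-JSON files are read through the
#' biomformat package.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param samples_as_rows logical; `TRUE` if the TSV stores samples as rows.
#' @return integer matrix, samples x OTUs, with dimnames.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom-json"),
                           samples_as_rows = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("biomformat is required to read BIOM files", call. = FALSE)
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # OTUs x samples
    return(validate_otu_counts(t(m)))
  }
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t", quote = "",
    check.names = FALSE, colClasses = "character"
  )
  if (ncol(df) < 2) stop("TSV table has no sample columns", call. = FALSE)
  ids <- df[[1]]
  hdr <- colnames(df)[-1]
  row_role <- if (samples_as_rows) "sample" else "OTU"
  col_role <- if (samples_as_rows) "OTU" else "sample"
  if (anyDuplicated(ids)) {
    stopf("duplicate %s id(s): %s", row_role,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  if (anyDuplicated(hdr)) {
    stopf("duplicate %s id(s): %s", col_role,
      paste(unique(hdr[duplicated(hdr)]), collapse = ", ")
    )
  }
  raw <- as.matrix(df[, -1, drop = FALSE])
  colnames(raw) <- hdr
  num <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(num) & !(is.na(raw) | toupper(raw) == "NA"))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(raw))
    stopf(
      "non-numeric cell '%s' at row '%s', column '%s'",
      raw[bad[1]], ids[rc[1, 1]], colnames(raw)[rc[1, 2]]
    )
  }
  counts <- matrix(num, nrow = nrow(raw), dimnames = list(ids, colnames(raw)))
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stopf(
      "negative count at row '%s', column '%s'",
      ids[neg[1, 1]], colnames(raw)[neg[1, 2]]
    )
  }
  if (!samples_as_rows) counts <- t(counts)
  validate_otu_counts(counts)
}

#' Write a sample x OTU count table as TSV
#'
#' Inverse of [read_otu_table()]: OTUs as file rows, first column `otu_id`,
#' header row of sample ids. Round-trips are bit-identical.
#'
#' @param counts samples x OTUs integer matrix.
#' @param path output path.
#' @export
write_otu_table <- function(counts, path) {
  counts <- validate_otu_counts(counts)
  m <- t(counts)
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read an OTU taxonomy table
#'
#' Format: two tab-separated columns, `otu_id` and a semicolon-joined
#' lineage of up to 7 ranks (kingdom..species). Missing trailing ranks are
#' filled with `NA` (fully unknown).
#'
#' @param path file path.
#' @return data.frame with columns `otu_id` and the seven ranks.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t", quote = "",
    check.names = FALSE, colClasses = "character"
  )
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stopf("duplicate OTU id(s) in taxonomy: %s", paste(dup, collapse = ", "))
  }
  parts <- strsplit(df[[2]], ";", fixed = TRUE)
  ranks <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p[p == ""] <- NA_character_
    length(p) <- 7L
    p
  }, character(7)))
  colnames(ranks) <- TAXONOMY_RANKS
  out <- data.frame(otu_id = ids, ranks, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write an OTU taxonomy table
#' @param taxonomy data.frame as returned by [read_taxonomy()].
#' @param path output path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  lin <- apply(as.matrix(taxonomy[, TAXONOMY_RANKS, drop = FALSE]), 1,
    function(p) paste(ifelse(is.na(p), "", p), collapse = ";")
  )
  lin <- sub(";+$", "", lin)
  utils::write.table(
    data.frame(otu_id = taxonomy$otu_id, lineage = lin),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Read sample metadata
#'
#' Expected columns: `sample_id`, `sample_type`, `species`, `site`,
#' `landuse`, `delta15N_animal`, `delta15N_litter`. Soil samples carry `NA`
#' in `delta15N_animal`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t", quote = "",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (!"sample_id" %in% names(df)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    stopf("duplicate sample id(s) in metadata: %s", paste(dup, collapse = ", "))
  }
  df
}

#' Write sample metadata
#' @param metadata data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Remove OTUs with low total read count
#'
#' Drops OTUs whose read total across all samples (soils and animals
#' pooled) is below `min_total`; retains exactly the OTUs with column sum
#' `>= min_total`. The sample set is unchanged. Idempotent.
#'
#' @param counts samples x OTUs matrix.
#' @param min_total minimum total reads per OTU (default 100).
#' @return filtered matrix.
#' @export
filter_low_count_otus <- function(counts, min_total = 100) {
  counts <- validate_otu_counts(counts)
  if (!is.numeric(min_total) || length(min_total) != 1 || min_total < 0) {
    stop("`min_total` must be a single non-negative number", call. = FALSE)
  }
  counts[, colSums(counts) >= min_total, drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Samples with fewer than `depth` reads are discarded and reported; each
#' retained sample is subsampled without replacement to exactly `depth`
#' reads (seeded, via `vegan::rrarefy`).
#'
#' @param counts samples x OTUs matrix.
#' @param depth target read depth (>= 1).
#' @param seed integer seed or `NULL`.
#' @return list with `table` (rarefied matrix) and `discarded_sample_ids`.
#' @export
rarefy_table <- function(counts, depth, seed = NULL) {
  counts <- validate_otu_counts(counts)
  if (!is.numeric(depth) || length(depth) != 1 || depth < 1) {
    stop("`depth` must be a single integer >= 1", call. = FALSE)
  }
  depth <- as.integer(depth)
  totals <- rowSums(counts)
  discard <- rownames(counts)[totals < depth]
  keep <- counts[totals >= depth, , drop = FALSE]
  if (nrow(keep) > 0) {
    rar <- with_seed(seed, suppressWarnings(vegan::rrarefy(keep, depth)))
    rar <- matrix(as.integer(rar),
      nrow = nrow(keep),
      dimnames = dimnames(keep)
    )
  } else {
    rar <- keep
  }
  list(table = rar, discarded_sample_ids = discard)
}

#' Read an OTU phylogeny from a newick file
#' @param path newick file.
#' @return an `ape::phylo` tree.
#' @export
read_otu_tree <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tree <- ape::read.tree(path)
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
    any(tree$edge.length < 0)) {
    stop("tree must have finite non-negative branch lengths", call. = FALSE)
  }
  tree
}

#' Write an OTU phylogeny to a newick file
#' @param tree an `ape::phylo` tree.
#' @param path output path.
#' @export
write_otu_tree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}
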