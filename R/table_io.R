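#' Construct an abundance table
#'
#' The central container of the package: a samples x taxa matrix of
#' non-negative counts (or proportions, after [relative_abundance()]) for one
#' kingdom, with optional QIIME-style taxonomy lineage strings per taxon.
#' Internally samples are rows; the common on-disk amplicon layout
#' (taxa rows x sample columns) is transposed at the I/O boundary.
#'
#' @param counts numeric matrix, samples x taxa, with unique row (sample) and
#'   column (taxon) names. All entries must be finite and >= 0.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param taxonomy optional named character vector of semicolon-separated,
#'   rank-prefixed lineage strings (`"k__...; p__...; ...; g__..."`), named by
#'   taxon id. Taxa without an entry get `NA`.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(counts, kingdom = c("bacteria", "fungi"),
                            taxonomy = NULL) {
  kingdom <- match.arg(kingdom)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("counts must have sample (row) and taxon (column) names")
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  dup_t <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_t))
    stop("duplicate taxon ids: ", paste(dup_t, collapse = ", "))
  if (!is.numeric(counts)) {
    bad <- which(!apply(counts, 2, is.numeric))[1]
    stop("non-numeric abundance values in column '", colnames(counts)[bad], "'")
  }
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-finite count at [sample '",
         rownames(counts)[bad[1, 1]], "', taxon '",
         colnames(counts)[bad[1, 2]], "']")
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[match(colnames(counts), names(taxonomy))]
    names(taxonomy) <- colnames(counts)
  }
  structure(list(counts = counts, kingdom = kingdom, taxonomy = taxonomy),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %s: %d samples x %d taxa\n",
              x$kingdom, nrow(x$counts), ncol(x$counts)))
  cat("  total counts:", sum(x$counts),
      if (!is.null(x$taxonomy)) "| taxonomy attached" else "", "\n")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Sample and taxon identifiers
#' @param x an `abundance_table`
#' @return character vector of ids
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname sample_ids
#' @export
taxon_ids <- function(x) colnames(x$counts)

## replace the count matrix, keeping taxonomy aligned to surviving columns
at_replace <- function(x, counts) {
  tax <- if (is.null(x$taxonomy)) NULL else x$taxonomy[colnames(counts)]
  abundance_table(counts, x$kingdom, tax)
}

#' Read an abundance table from disk
#'
#' TSV files follow the classic amplicon layout: taxa in rows, samples in
#' columns, first column holding taxon ids.  BIOM files (JSON dialect) are
#' read through the biomformat package.
#'
#' @param path file path
#' @param format `"tsv"` or `"biom"`
#' @param kingdom `"bacteria"` or `"fungi"`
#' @param taxonomy optional path to a two-column TSV (taxon_id, lineage)
#' @return an [abundance_table()]
#' @export
read_table <- function(path, format = c("tsv", "biom"),
                       kingdom = c("bacteria", "fungi"), taxonomy = NULL) {
  format <- match.arg(format)
  kingdom <- match.arg(kingdom)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    raw <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                             stringsAsFactors = FALSE)
    taxa <- as.character(raw[[1]])
    m <- as.matrix(raw[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                     !is.na(m), arr.ind = TRUE)
      if (nrow(bad))
        stop("non-numeric cell at [taxon '", taxa[bad[1, 1]], "', sample '",
             colnames(m)[bad[1, 2]], "']")
      m <- array(as.numeric(m), dim(m), dimnames = dimnames(m))
    }
    rownames(m) <- taxa
    counts <- t(m)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as.matrix(biomformat::biom_data(b))  # taxa x samples
    counts <- t(m)
  }
  tax <- NULL
  if (!is.null(taxonomy)) {
    tt <- utils::read.delim(taxonomy, check.names = FALSE,
                            stringsAsFactors = FALSE)
    tax <- stats::setNames(as.character(tt[[2]]), as.character(tt[[1]]))
  }
  abundance_table(counts, kingdom, tax)
}

#' Write an abundance table to disk
#'
#' @inheritParams read_table
#' @param x an `abundance_table`
#' @param taxonomy_path optional path for a lineage TSV (written only when the
#'   table carries taxonomy)
#' @return `path`, invisibly
#' @export
write_table <- function(x, path, format = c("tsv", "biom"),
                        taxonomy_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    m <- t(x$counts)
    df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("writing BIOM files requires the 'biomformat' package")
    b <- biomformat::make_biom(t(x$counts))
    biomformat::write_biom(b, path)
  }
  if (!is.null(taxonomy_path) && !is.null(x$taxonomy)) {
    utils::write.table(
      data.frame(taxon_id = names(x$taxonomy), lineage = unname(x$taxonomy)),
      taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' @param path TSV with a `sample_id` column and a two-level `group` column
#' @param group_col name of the group column
#' @return data.frame with `sample_id` first and `group` as a factor
#' @export
read_metadata <- function(path, group_col = "group") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df, group_col)
}

validate_metadata <- function(df, group_col = "group") {
  if (!"sample_id" %in% names(df)) stop("metadata needs a 'sample_id' column")
  if (!group_col %in% names(df))
    stop("metadata needs a '", group_col, "' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata")
  df$group <- factor(df[[group_col]])
  if (nlevels(df$group) != 2L)
    stop("the group factor must have exactly two levels, found ",
         nlevels(df$group))
  df
}

#' Convert counts to relative abundances
#'
#' Each sample (row) is rescaled to sum to one.
#'
#' @param x an `abundance_table`
#' @return an `abundance_table` of proportions
#' @export
relative_abundance <- function(x) {
  tot <- rowSums(x$counts)
  zero <- which(tot <= 0)
  if (length(zero))
    stop("zero-sum sample(s): ", paste(sample_ids(x)[zero], collapse = ", "))
  at_replace(x, x$counts / tot)
}

#' Keep major genera by mean relative abundance
#'
#' Taxa whose mean relative abundance across samples is at or above
#' `threshold` (inclusive, default 1%) are retained.
#'
#' @param x an `abundance_table` (counts or proportions)
#' @param threshold proportion in (0, 1)
#' @return filtered `abundance_table`
#' @export
filter_major_genera <- function(x, threshold = 0.01) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  rel <- relative_abundance(x)
  keep <- colMeans(rel$counts) >= threshold
  at_replace(x, x$counts[, keep, drop = FALSE])
}

#' Prevalence filter
#'
#' Retains taxa detected (count > 0) in strictly more than `min_fraction` of
#' the samples — matching the "> 50%" / "> 20%" network pre-filters.
#'
#' @param x an `abundance_table`
#' @param min_fraction fraction in (0, 1); strict inequality
#' @return filtered `abundance_table` (possibly with zero taxa, with a warning)
#' @export
filter_prevalence <- function(x, min_fraction) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1 ||
      min_fraction <= 0 || min_fraction >= 1)
    stop("min_fraction must lie strictly inside (0, 1)")
  prev <- colMeans(x$counts > 0)
  keep <- prev > min_fraction
  if (!any(keep))
    warning("prevalence filter removed every taxon")
  at_replace(x, x$counts[, keep, drop = FALSE])
}

#' Align two kingdoms and metadata on their common samples
#'
#' Restricts both tables and the metadata to the intersection of their sample
#' ids, in the bacterial table's order.
#'
#' @param bact,fungi `abundance_table`s
#' @param meta metadata data.frame with a `sample_id` column
#' @return list with elements `bact`, `fungi`, `meta`
#' @export
align_kingdoms <- function(bact, fungi, meta) {
  common <- intersect(intersect(sample_ids(bact), sample_ids(fungi)),
                      meta$sample_id)
  if (!length(common))
    stop("no samples shared between the tables and metadata")
  common <- sample_ids(bact)[sample_ids(bact) %in% common]
  dropped <- setdiff(unique(c(sample_ids(bact), sample_ids(fungi),
                              meta$sample_id)), common)
  if (length(dropped))
    message("align_kingdoms: dropping ", length(dropped),
            " sample(s) absent from some input: ",
            paste(dropped, collapse = ", "))
  list(bact = at_replace(bact, bact$counts[common, , drop = FALSE]),
       fungi = at_replace(fungi, fungi$counts[common, , drop = FALSE]),
       meta = meta[match(common, meta$sample_id), , drop = FALSE])
}

## rank prefixes of QIIME-style lineage strings
.rank_prefixes <- c(kingdom = "k__", phylum = "p__", class = "c__",
                    order = "o__", family = "f__", genus = "g__",
                    species = "s__")

#' Parse QIIME-style lineage strings
#'
#' @param lineages character vector like `"k__Fungi; p__Ascomycota; g__Candida"`
#' @return character matrix, one row per lineage, columns kingdom..species;
#'   unassigned ranks are empty strings
#' @export
parse_lineage <- function(lineages) {
  out <- matrix("", length(lineages), length(.rank_prefixes),
                dimnames = list(names(lineages), names(.rank_prefixes)))
  for (i in seq_along(lineages)) {
    if (is.na(lineages[i])) next
    parts <- trimws(strsplit(lineages[i], ";", fixed = TRUE)[[1]])
    for (p in parts) {
      hit <- which(startsWith(p, .rank_prefixes))
      if (length(hit))
        out[i, hit[1]] <- sub("^.__", "", p)
    }
  }
  out
}

#' Collapse an abundance table at a taxonomic rank
#'
#' Sums counts over taxa sharing the same name at `rank` (taxonomy required).
#' Taxa unassigned at that rank are dropped with a message.
#'
#' @param x an `abundance_table` with taxonomy
#' @param rank one of kingdom, phylum, class, order, family, genus, species
#' @return collapsed `abundance_table` (no taxonomy attached)
#' @export
collapse_rank <- function(x, rank = "genus") {
  rank <- match.arg(rank, names(.rank_prefixes))
  if (is.null(x$taxonomy)) stop("table has no taxonomy to collapse on")
  ranks <- parse_lineage(x$taxonomy)
  name <- ranks[, rank]
  keep <- !is.na(name) & nzchar(name)
  if (!all(keep))
    message("collapse_rank: dropping ", sum(!keep),
            " taxa unassigned at rank ", rank)
  if (!any(keep)) stop("no taxa assigned at rank ", rank)
  m <- x$counts[, keep, drop = FALSE]
  grp <- factor(name[keep], levels = unique(name[keep]))
  collapsed <- sapply(levels(grp), function(g)
    rowSums(m[, grp == g, drop = FALSE]))
  if (is.null(dim(collapsed)))
    collapsed <- matrix(collapsed, nrow = nrow(m),
                        dimnames = list(rownames(m), levels(grp)))
  abundance_table(collapsed, x$kingdom)
}
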