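# Sample/OTU retention rules, trophic annotation from a literature rule
# table, relative-abundance series and summary fractions.

#' Drop samples with too few reads
#'
#' Retains exactly the samples whose total read count is at least
#' `min_reads` (sequencing-depth quality filter; the study convention is
#' 10,000 reads). The OTU set is unchanged.
#'
#' @param table an [otu_table].
#' @param min_reads non-negative integer.
#' @return filtered [otu_table].
#' @export
filter_samples_min_reads <- function(table, min_reads = 10000) {
  stopifnot(inherits(table, "otu_table"), min_reads >= 0)
  keep <- colSums(table$counts) >= min_reads
  if (!any(keep))
    warning("all samples removed by min_reads = ", min_reads)
  structure(list(counts = table$counts[, keep, drop = FALSE],
                 sample_dates = table$sample_dates[keep]),
            class = "otu_table")
}

#' Minimum total-count cut-off implied by a global abundance fraction
#'
#' The smallest integer count `c` with `c >= fraction * total_reads`, i.e.
#' `ceiling(fraction * total_reads)`. With the study's 20,476,979 total reads
#' and a fraction of 0.001% this gives the 205-read cut-off.
#'
#' @param total_reads grand total read count (>= 0).
#' @param fraction proportion in `[0, 1]`.
#' @return integer cut-off.
#' @export
#' @examples
#' global_threshold_min_count(20476979, 1e-5)
global_threshold_min_count <- function(total_reads, fraction) {
  stopifnot(total_reads >= 0, fraction >= 0, fraction <= 1)
  # tiny slack so products that are mathematically integral do not round up
  as.integer(max(0, ceiling(fraction * total_reads - 1e-9)))
}

#' Drop OTUs below a global relative-abundance threshold
#'
#' Retains exactly the OTUs whose total read count across all samples reaches
#' [global_threshold_min_count()]. The reference total defaults to the grand
#' total of `table` itself; pass `total_reads` to threshold against the grand
#' total of an unfiltered dataset (the study applies 0.001% of the full
#' dataset's reads).
#'
#' @param table an [otu_table].
#' @param fraction proportion in `[0, 1]`.
#' @param total_reads reference grand total; default `otu_grand_total(table)`.
#' @return filtered [otu_table].
#' @export
apply_global_threshold <- function(table, fraction,
                                   total_reads = otu_grand_total(table)) {
  stopifnot(inherits(table, "otu_table"))
  min_count <- global_threshold_min_count(total_reads, fraction)
  keep <- rowSums(table$counts) >= min_count
  structure(list(counts = table$counts[keep, , drop = FALSE],
                 sample_dates = table$sample_dates),
            class = "otu_table")
}

# ---------------------------------------------------------------------------
# trophic annotation

#' Read a trophic rule table
#'
#' Tab-separated with columns `rank`, `pattern`, `label`, `source`: ordered
#' literature-derived rules mapping a taxon name (exact or prefix match) at a
#' given rank to a trophic label (`parasitoid`, `non_parasitoid`, `unknown`),
#' with a citation key recording provenance.
#'
#' @param path file path.
#' @return `data.frame` of rules in file order.
#' @export
read_trophic_lookup <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  trophic_lookup(df$rank, df$pattern, df$label, df$source)
}

#' @rdname read_trophic_lookup
#' @param rank,pattern,label,source rule columns (recycled to equal length).
#' @export
trophic_lookup <- function(rank, pattern, label, source = "") {
  df <- data.frame(rank = as.character(rank), pattern = as.character(pattern),
                   label = as.character(label),
                   source = rep_len(as.character(source), length(rank)),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$pattern))) stop_validation("empty pattern in trophic rule")
  bad <- setdiff(df$label, c("parasitoid", "non_parasitoid", "unknown"))
  if (length(bad)) stop_validation("unknown trophic label(s): ",
                                   paste(bad, collapse = ", "))
  if (any(!df$rank %in% pr2_ranks()))
    stop_validation("rule rank not in rank scheme: ",
                    paste(setdiff(df$rank, pr2_ranks()), collapse = ", "))
  df
}

#' @rdname read_trophic_lookup
#' @param lookup a rule `data.frame`.
#' @export
write_trophic_lookup <- function(lookup, path) {
  utils::write.table(lookup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate OTUs with trophic modes from literature rules
#'
#' Each OTU's lineage is scanned most-specific-rank-first (species towards
#' kingdom); at each rank the rules for that rank are tried in file order and
#' the first whose pattern matches the taxon name (exactly or as a prefix)
#' assigns the label. OTUs matching no rule are labelled `unknown`.
#'
#' @param taxonomy taxonomy `data.frame` (see [taxonomy_table()]).
#' @param lookup rule `data.frame` (see [trophic_lookup()]).
#' @param ranks rank scheme used by both tables.
#' @return `data.frame` with columns `otu_id`, `label`, `matched_rank`,
#'   `matched_rule` (pattern) and `source`.
#' @export
annotate_trophic <- function(taxonomy, lookup, ranks = pr2_ranks()) {
  if (nrow(lookup) == 0) stop_validation("empty trophic lookup")
  rank_order <- rev(ranks)            # most specific first
  out <- data.frame(otu_id = taxonomy$otu_id, label = "unknown",
                    matched_rank = NA_character_, matched_rule = NA_character_,
                    source = NA_character_, stringsAsFactors = FALSE)
  for (rk in rank_order) {
    rules <- lookup[lookup$rank == rk, , drop = FALSE]
    if (nrow(rules) == 0 || !rk %in% names(taxonomy)) next
    names_at_rank <- taxonomy[[rk]]
    for (j in seq_len(nrow(rules))) {
      hit <- is.na(out$matched_rank) & nzchar(names_at_rank) &
        startsWith(names_at_rank, rules$pattern[j])
      if (any(hit)) {
        out$label[hit] <- rules$label[j]
        out$matched_rank[hit] <- rk
        out$matched_rule[hit] <- rules$pattern[j]
        out$source[hit] <- rules$source[j]
      }
    }
  }
  out
}

#' Summarise trophic annotation
#'
#' Counts and percentages of parasitoid and unknown-mode OTUs; percentages
#' are `100 * count / total` rounded half-away-from-zero to one decimal (the
#' convention used for printed survey fractions such as 10.2% and 16.5%).
#'
#' @param labels character vector of per-OTU trophic labels.
#' @return list of class `annotation_summary` with fields `n_otus_total`,
#'   `n_parasitoid`, `n_unknown`, `pct_parasitoid`, `pct_unknown`.
#' @export
annotation_summary <- function(labels) {
  n <- length(labels)
  if (n == 0) stop_validation("need at least one OTU")
  n_par <- sum(labels == "parasitoid")
  n_unk <- sum(labels == "unknown")
  structure(list(n_otus_total = n, n_parasitoid = n_par, n_unknown = n_unk,
                 pct_parasitoid = round_half_away(100 * n_par / n, 1),
                 pct_unknown = round_half_away(100 * n_unk / n, 1)),
            class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf("%d OTUs: %d parasitoid (%.1f%%), %d unknown trophic mode (%.1f%%)\n",
              x$n_otus_total, x$n_parasitoid, x$pct_parasitoid,
              x$n_unknown, x$pct_unknown))
  invisible(x)
}

# ---------------------------------------------------------------------------
# relative abundance

#' A dated relative-abundance series
#'
#' @param dates `Date` vector (sorted).
#' @param values fractions in `[0, 1]` (NA where the denominator was zero).
#' @param subject OTU id or group label.
#' @param denominator_mode one of `all_reads`, `parasitoid_reads`, `custom`.
#' @return object of class `abundance_series`.
#' @export
abundance_series <- function(dates, values, subject = "",
                             denominator_mode = "all_reads") {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(values), !is.unsorted(dates))
  if (any(!is.na(values) & (values < -1e-12 | values > 1 + 1e-12)))
    stop_validation("relative abundances must lie in [0, 1]")
  structure(list(dates = dates, values = as.numeric(values),
                 subject = subject, denominator_mode = denominator_mode),
            class = "abundance_series")
}

#' @export
print.abundance_series <- function(x, ...) {
  cat(sprintf("abundance_series '%s' (%s): %d samples, max %.4g\n",
              x$subject, x$denominator_mode, length(x$dates),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Relative-abundance series per OTU or group
#'
#' For each subject, `value(sample) = reads(subject) / reads(denominator
#' set)`. The denominator is all reads in the sample (`all_reads`), the reads
#' of a supplied subset (`custom`, e.g. parasitoid reads only, as in
#' parasitoid-community composition plots), or the subjects themselves.
#' Groups (named list of OTU id vectors) are summed before division. Samples
#' where the denominator is zero get `NA` with a warning.
#'
#' @param table an [otu_table].
#' @param subjects character vector of OTU ids, or a named list mapping group
#'   labels to member OTU ids. Default: all OTUs.
#' @param denominator_mode `"all_reads"` or `"custom"`.
#' @param denominator_otus OTU ids forming the denominator when
#'   `denominator_mode = "custom"`.
#' @return named list of [abundance_series], one per subject.
#' @export
relative_abundance <- function(table, subjects = otu_ids(table),
                               denominator_mode = c("all_reads", "custom"),
                               denominator_otus = NULL) {
  stopifnot(inherits(table, "otu_table"))
  denominator_mode <- match.arg(denominator_mode)
  counts <- table$counts
  if (is.list(subjects)) {
    members <- unlist(subjects, use.names = FALSE)
  } else {
    subjects <- stats::setNames(as.list(subjects), subjects)
    members <- unlist(subjects, use.names = FALSE)
  }
  missing_ids <- setdiff(members, rownames(counts))
  if (length(missing_ids))
    stop_validation("subject OTUs not in table: ",
                    paste(missing_ids, collapse = ", "))
  denom <- if (denominator_mode == "all_reads") colSums(counts)
           else {
             if (is.null(denominator_otus))
               stop_validation("denominator_otus required for custom mode")
             colSums(counts[intersect(denominator_otus, rownames(counts)), ,
                            drop = FALSE])
           }
  if (any(denom == 0))
    warning(sum(denom == 0), " sample(s) with zero denominator; values set NA")
  denom[denom == 0] <- NA_real_
  mode_label <- if (denominator_mode == "all_reads") "all_reads" else "custom"
  lapply(stats::setNames(names(subjects), names(subjects)), function(g) {
    num <- colSums(counts[subjects[[g]], , drop = FALSE])
    abundance_series(table$sample_dates, num / denom, subject = g,
                     denominator_mode = mode_label)
  })
}

#' Aggregate an OTU table by taxon at a rank
#'
#' Sums counts over OTUs sharing the taxon name at `rank`; OTUs unassigned at
#' that rank are grouped under `"unassigned"`. Reads are conserved exactly.
#'
#' @param table an [otu_table].
#' @param taxonomy taxonomy `data.frame` covering the table's OTUs.
#' @param rank rank name from the scheme used in `taxonomy`.
#' @return an [otu_table] whose rows are taxon groups.
#' @export
aggregate_by_taxon <- function(table, taxonomy, rank) {
  stopifnot(inherits(table, "otu_table"))
  if (!rank %in% names(taxonomy)) stop_validation("unknown rank: ", rank)
  idx <- match(otu_ids(table), taxonomy$otu_id)
  if (anyNA(idx))
    stop_validation("OTUs missing from taxonomy: ",
                    paste(otu_ids(table)[is.na(idx)][1:min(5, sum(is.na(idx)))],
                          collapse = ", "))
  grp <- taxonomy[[rank]][idx]
  grp[!nzchar(grp) | is.na(grp)] <- "unassigned"
  agg <- rowsum(table$counts, group = grp, reorder = TRUE)
  structure(list(counts = agg, sample_dates = table$sample_dates),
            class = "otu_table")
}

#' OTU counts per taxon at a rank
#'
#' Number of OTUs carrying each taxon name at `rank` (the "OTU Count" column
#' of diversity-overview tables); unassigned OTUs are grouped under
#' `"unassigned"`.
#'
#' @param taxonomy taxonomy `data.frame`.
#' @param rank rank name.
#' @return named integer vector, decreasing.
#' @export
count_otus_by_rank <- function(taxonomy, rank) {
  if (!rank %in% names(taxonomy)) stop_validation("unknown rank: ", rank)
  grp <- taxonomy[[rank]]
  grp[!nzchar(grp) | is.na(grp)] <- "unassigned"
  sort(table(grp), decreasing = TRUE)
}
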