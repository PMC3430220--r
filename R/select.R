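# Correlation analysis against the experimental BDE and selection of one
# representative descriptor per cluster.

#' Pearson correlation with validation
#'
#' @param x,y Numeric vectors of equal length >= 3; neither may be
#'   constant (the coefficient is undefined).
#' @return The sample Pearson correlation.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  cor(x, y)
}

#' Correlation of each descriptor with the experimental BDE
#'
#' Computed on the training rows only; Pearson r is invariant to the
#' affine normalization applied later, so raw descriptor values are used.
#'
#' @param table A [descriptor_table()].
#' @return A data.frame with one row per canonical descriptor:
#'   `descriptor`, `r`, `abs_r`.
#' @export
correlation_report <- function(table) {
  stopifnot(inherits(table, "descriptor_table"))
  tr <- as.data.frame(table)[table$split == "train", ]
  r <- vapply(canonical_descriptors(),
              function(d) pearson_r(tr[[d]], tr$expt_bde), 0.0)
  data.frame(descriptor = canonical_descriptors(),
             r = unname(r), abs_r = unname(abs(r)),
             stringsAsFactors = FALSE)
}

#' Select one representative descriptor per cluster
#'
#' Singleton groups pass through; from a multi-member group the member with
#' the largest absolute correlation with experiment is kept. Ties go to
#' canonical order. The chosen list is returned in canonical order.
#'
#' @param partition A partition of descriptor names (see [as_partition()]).
#' @param report A [correlation_report()] data.frame, or a named numeric
#'   vector of correlations.
#' @return List with class `selection_result`: `partition`, `chosen`
#'   (character, canonical order), `provenance` (one row per group:
#'   members, chosen, whether the group was a singleton).
#' @export
select_representatives <- function(partition, report) {
  if (is.numeric(report))
    report <- data.frame(descriptor = names(report), r = unname(report),
                         abs_r = abs(unname(report)), stringsAsFactors = FALSE)
  members <- unlist(partition)
  missing <- setdiff(members, report$descriptor)
  if (length(missing) > 0)
    stop("descriptor(s) missing from the correlation report: ",
         paste(missing, collapse = ", "))
  canon <- canonical_descriptors()
  pick <- function(group) {
    group <- group[order(match(group, canon))]   # canonical order breaks ties
    absr <- report$abs_r[match(group, report$descriptor)]
    group[which.max(absr)]
  }
  chosen <- vapply(partition, pick, "")
  prov <- data.frame(
    members = vapply(partition, function(g) paste(sort(g), collapse = "+"), ""),
    chosen = chosen,
    singleton = lengths(partition) == 1L,
    stringsAsFactors = FALSE)
  structure(list(partition = partition,
                 chosen = canon[canon %in% chosen],
                 provenance = prov),
            class = "selection_result")
}

#' Are several partitions identical (label-invariantly)?
#'
#' @param partitions List of at least two partitions.
#' @return `TRUE` iff all partitions are equal up to relabeling.
#' @export
partitions_stable <- function(partitions) {
  stopifnot(length(partitions) >= 2)
  sigs <- vapply(partitions, partition_signature, "")
  all(sigs == sigs[1])
}

#' Smallest step count from which the partition ladder is stable
#'
#' Given partitions observed at increasing training-step counts, returns
#' the smallest step count from which all later partitions agree with it,
#' or `NA` if even the final two differ.
#'
#' @param partitions List of partitions, parallel to `steps`.
#' @param steps Increasing integer step counts.
#' @return One of `steps`, or `NA_integer_`.
#' @export
first_stable_step <- function(partitions, steps) {
  stopifnot(length(partitions) == length(steps), !is.unsorted(steps))
  sigs <- vapply(partitions, partition_signature, "")
  for (i in seq_len(length(sigs) - 1)) {
    if (all(sigs[i:length(sigs)] == sigs[i])) return(steps[i])
  }
  NA_integer_
}
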