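# Packaged transcriptions of the benchmark deviation table (92 molecules x
# 6 methods) and the descriptor cluster-label table (2 basis sets x 7 step
# counts). Each loader verifies an md5 checksum so a corrupted installation
# fails loudly rather than silently shifting a statistic.

.fixture_md5 <- c(
  table1_deviations.csv    = "777d643336e244c09323904dc1eb2e6d",
  table2_cluster_labels.csv = "bce689e2416aae08eca2f999faab9a52"
)

.fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "sofmrbf")
  if (path == "")
    stop("fixture '", file, "' not found in installed package")
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[file]])))
    stop("fixture '", file, "' failed its checksum (got ", sum, ")")
  path
}

#' Per-molecule deviation fixture for the 92-molecule benchmark
#'
#' Deviations (calculated minus experimental homolysis BDE, kcal/mol) of 92
#' organic NO-carrier molecules under six methods: raw B3LYP with the
#' 6-31G(d) and STO-3G basis sets, and the RBF-corrected variants with all
#' twelve descriptors (DFT-RBFNN) or the cluster-selected subset
#' (DFT-SOFM-RBFNN). The twelve molecules held out as the test set are
#' flagged `is_test`.
#'
#' @return A data.frame with class `deviation_table`: `molecule_id`,
#'   `is_test`, and the six deviation columns `b3lyp_631gd`, `b3lyp_sto3g`,
#'   `dft_rbfnn_631gd`, `dft_rbfnn_sto3g`, `dft_sofm_rbfnn_631gd`,
#'   `dft_sofm_rbfnn_sto3g`.
#' @export
#' @examples
#' t1 <- load_table1_fixture()
#' mean(abs(t1$b3lyp_631gd))  # raw 6-31G(d) mean absolute deviation
load_table1_fixture <- function() {
  df <- read.csv(.fixture_path("table1_deviations.csv"),
                 stringsAsFactors = FALSE)
  df$molecule_id <- as.character(df$molecule_id)
  stopifnot(nrow(df) == 92, is.logical(df$is_test))
  class(df) <- c("deviation_table", "data.frame")
  df
}

#' Descriptor cluster-label fixture
#'
#' Winning-neuron indices (on the 6 x 4 competitive grid, so 1..24) assigned
#' to each of the twelve canonical descriptors by the SOFM at increasing
#' training-step counts, for descriptors computed with either basis set.
#'
#' @return A data.frame: `basis` (`"6-31G(d)"` or `"STO-3G"`),
#'   `training_steps`, then one integer label column per canonical
#'   descriptor. 14 records (7 step counts x 2 bases).
#' @seealso [cluster_labels()] to extract one record as a named vector,
#'   [labels_to_partition()] to turn labels into a partition.
#' @export
load_table2_fixture <- function() {
  df <- read.csv(.fixture_path("table2_cluster_labels.csv"),
                 check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 14,
            identical(names(df)[-(1:2)], canonical_descriptors()))
  lab <- as.matrix(df[, canonical_descriptors()])
  if (any(lab < 1 | lab > 24))
    stop("fixture labels outside the 1..24 neuron grid")
  df
}

#' Extract one cluster-label record
#'
#' @param fixture Result of [load_table2_fixture()].
#' @param basis `"6-31G(d)"` or `"STO-3G"`.
#' @param steps Training-step count of the record.
#' @return Named integer vector of winning-neuron indices, one per
#'   canonical descriptor.
#' @export
cluster_labels <- function(fixture, basis, steps) {
  row <- fixture$basis == basis & fixture$training_steps == steps
  if (sum(row) != 1)
    stop("no unique record for basis '", basis, "' at ", steps, " steps")
  labs <- as.integer(fixture[row, canonical_descriptors()])
  setNames(labs, canonical_descriptors())
}
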