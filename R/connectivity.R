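#' Scan conditions recognised by the pipeline
#'
#' The seven scan conditions of the cognitive-control protocol: three
#' working-memory loads (0/1/2-back), the initiation and inhibition
#' conditions of the go/no-go task, the shifting task, and task-free rest.
#'
#' @return Character vector of condition identifiers, rest last.
#' @export
ne_conditions <- function() {
  c("nback0", "nback1", "nback2",
    "gng_initiation", "gng_inhibition", "shifting", "rest")
}

#' Canonical functional network labels
#'
#' Ten canonical resting-state networks commonly used with volumetric
#' parcellations: auditory (AUD), cingulo-opercular (COP), dorsal
#' attention (DAN), default mode (DMN), frontoparietal (FPC), salience
#' (SAL), somatomotor (SM), subcortical (SC), ventral attention (VAN)
#' and visual (VIS).
#'
#' @param n Number of labels requested; labels beyond the canonical ten
#'   are generated as `"NET11"`, `"NET12"`, ...
#' @return Character vector of length `n`.
#' @export
ne_networks <- function(n = 10L) {
  base <- c("AUD", "COP", "DAN", "DMN", "FPC", "SAL", "SM", "SC", "VAN", "VIS")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("NET%d", seq.int(length(base) + 1L, n)))
}

#' Scope label for the whole-brain network
#' @return The string `"whole_brain"`.
#' @export
whole_brain <- function() "whole_brain"

#' Construct and validate a signed connectivity matrix
#'
#' Wraps a square symmetric signed weight matrix (typically a Pearson
#' correlation matrix between regional activity time series) together
#' with region identifiers and scan metadata. Validation enforces the
#' invariants the energy statistic relies on:
#' \itemize{
#'   \item square with at least 3 regions;
#'   \item all off-diagonal weights finite;
#'   \item symmetric within `asym_tol` (then symmetrised by averaging);
#'   \item diagonal zeroed (self-connections form no triangle; raw
#'     correlation matrices carry 1s on the diagonal);
#'   \item off-diagonal weights in \eqn{[-1, 1]} unless
#'     `allow_out_of_range = TRUE` (e.g. Fisher-z transformed input).
#' }
#'
#' @param weights Square numeric matrix of signed connection weights.
#' @param region_ids Optional character vector of region identifiers;
#'   defaults to existing dimnames or `"R001"`, `"R002"`, ...
#' @param subject_id Optional subject label.
#' @param condition Optional condition label (see [ne_conditions()]).
#' @param allow_out_of_range Allow off-diagonal weights outside
#'   \eqn{[-1, 1]}. The energy formula itself does not require the bound,
#'   but the \eqn{[-1, 1]} range guarantee on the energy does.
#' @param asym_tol Maximum tolerated absolute asymmetry before erroring.
#' @return An object of class `connectivity_matrix`: a list with
#'   elements `weights`, `region_ids`, `subject_id`, `condition`, `n`.
#' @examples
#' w <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3)
#' m <- connectivity_matrix(w)
#' network_energy(m)  # -1: a single balanced triangle at unit intensity
#' @export
connectivity_matrix <- function(weights, region_ids = NULL,
                                subject_id = NA_character_,
                                condition = NA_character_,
                                allow_out_of_range = FALSE,
                                asym_tol = 1e-8) {
  if (inherits(weights, "connectivity_matrix")) return(weights)
  weights <- as.matrix(weights)
  if (!is.numeric(weights)) stop("weights must be numeric")
  n <- nrow(weights)
  if (n != ncol(weights)) stop("weights must be square")
  if (n < 3L) stop("connectivity matrix needs at least 3 regions (N >= 3)")
  offdiag <- weights[row(weights) != col(weights)]
  if (any(!is.finite(offdiag)))
    stop("non-finite off-diagonal weight(s) in connectivity matrix")
  asym <- max(abs(weights - t(weights)), na.rm = TRUE)
  if (asym > asym_tol)
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, asym_tol))
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (!allow_out_of_range && max(abs(weights)) > 1 + 1e-8)
    stop("off-diagonal weights outside [-1, 1]; use allow_out_of_range = TRUE ",
         "for Fisher-z or otherwise unbounded weights")
  if (is.null(region_ids)) {
    region_ids <- rownames(weights)
    if (is.null(region_ids)) region_ids <- sprintf("R%03d", seq_len(n))
  }
  if (length(region_ids) != n) stop("region_ids length must equal nrow(weights)")
  dimnames(weights) <- list(region_ids, region_ids)
  structure(
    list(weights = weights, region_ids = as.character(region_ids),
         subject_id = subject_id, condition = condition, n = n),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d regions, subject=%s, condition=%s\n",
              x$n, x$subject_id, x$condition))
  cat(sprintf("  weight range [%.3f, %.3f]\n",
              min(x$weights[row(x$weights) != col(x$weights)]),
              max(x$weights[row(x$weights) != col(x$weights)])))
  invisible(x)
}

#' Construct a parcellation (region to canonical-network map)
#'
#' @param region_id Character vector of region identifiers.
#' @param network_label Character vector, same length, giving each
#'   region's canonical network.
#' @param atlas_name Optional atlas label (e.g. the parcellation family).
#' @return A `parcellation` object (data.frame with attribute
#'   `atlas_name`).
#' @export
parcellation <- function(region_id, network_label, atlas_name = "custom") {
  region_id <- as.character(region_id)
  network_label <- as.character(network_label)
  if (length(region_id) != length(network_label))
    stop("region_id and network_label must have equal length")
  if (anyDuplicated(region_id))
    stop("duplicated region_id in parcellation")
  if (any(is.na(network_label)))
    stop("every region must have exactly one network label")
  p <- data.frame(region_id = region_id, network_label = network_label,
                  stringsAsFactors = FALSE)
  attr(p, "atlas_name") <- atlas_name
  class(p) <- c("parcellation", class(p))
  p
}

#' Regions belonging to one scope of a parcellation
#'
#' @param p A [parcellation()].
#' @param scope A canonical network label, or [whole_brain()] /
#'   `"whole"` for all regions.
#' @param min_size Minimum number of member regions (a triangle needs 3).
#' @return Character vector of region ids.
#' @export
scope_regions <- function(p, scope, min_size = 3L) {
  if (scope %in% c(whole_brain(), "whole")) return(p$region_id)
  idx <- p$network_label == scope
  if (!any(idx)) stop(sprintf("scope '%s' not present in parcellation", scope))
  ids <- p$region_id[idx]
  if (length(ids) < min_size)
    stop(sprintf("scope '%s' has %d regions; at least %d required",
                 scope, length(ids), min_size))
  ids
}

#' Read a square connectivity matrix from CSV/TSV
#'
#' Accepts headerless or headered square numeric tables. Separator is
#' inferred from the extension (`.tsv`/`.txt` = tab, otherwise comma).
#' Filenames of the form `<subject>_<condition>.csv` have subject and
#' condition parsed out; the condition is matched as the longest known
#' suffix so subject labels may themselves contain underscores.
#'
#' @param path File path.
#' @param ... Passed to [connectivity_matrix()].
#' @return A `connectivity_matrix`.
#' @export
read_connectivity <- function(path, ...) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  first <- readLines(path, n = 1L)
  cells <- strsplit(first, sep, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(cells))))
  tab <- utils::read.table(path, sep = sep, header = has_header,
                           row.names = if (has_header) 1L else NULL,
                           check.names = FALSE)
  meta <- parse_matrix_filename(basename(path))
  connectivity_matrix(as.matrix(tab), subject_id = meta$subject,
                      condition = meta$condition, ...)
}

parse_matrix_filename <- function(fname) {
  stem <- sub("\\.(csv|tsv|txt)$", "", fname, ignore.case = TRUE)
  for (cond in ne_conditions()) {
    suf <- paste0("_", cond)
    if (endsWith(stem, suf))
      return(list(subject = substr(stem, 1L, nchar(stem) - nchar(suf)),
                  condition = cond))
  }
  list(subject = stem, condition = NA_character_)
}

#' Read all `<subject>_<condition>` matrices in a directory
#'
#' @param dir Directory containing one CSV/TSV per subject x condition.
#' @param ... Passed to [read_connectivity()].
#' @return Nested named list: `cohort[[subject]][[condition]]`.
#' @export
read_matrix_dir <- function(dir, ...) {
  files <- list.files(dir, pattern = "\\.(csv|tsv|txt)$", full.names = TRUE)
  # only `<subject>_<condition>` files are matrices; sidecars
  # (parcellation, metadata) are skipped
  keep <- vapply(files, function(f)
    !is.na(parse_matrix_filename(basename(f))$condition), logical(1))
  files <- files[keep]
  if (length(files) == 0L) stop(sprintf("no matrix files found in %s", dir))
  cohort <- list()
  for (f in files) {
    m <- read_connectivity(f, ...)
    cohort[[m$subject_id]][[m$condition]] <- m
  }
  cohort
}

#' Read a parcellation TSV (columns region_id, network_label)
#' @param path File path.
#' @param atlas_name Atlas label to attach.
#' @return A `parcellation`.
#' @export
read_parcellation <- function(path, atlas_name = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("region_id", "network_label") %in% names(tab)))
    stop("parcellation file must have columns region_id, network_label")
  parcellation(tab$region_id, tab$network_label, atlas_name = atlas_name)
}

#' Write a parcellation TSV
#' @param p A [parcellation()].
#' @param path Output path.
#' @export
write_parcellation <- function(p, path) {
  utils::write.table(as.data.frame(p)[, c("region_id", "network_label")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
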