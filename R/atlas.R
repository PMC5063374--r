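#' Build a two-hemisphere region atlas with homotopic pairing
#'
#' Creates the canonical parcellation layout used throughout the package:
#' regions `1..n/2` form the left hemisphere, regions `n/2+1..n` the right,
#' and region `i` on the left is homotopically paired with its mirror region
#' `i + n/2` on the right. The pairing is an involution with no fixed points
#' and always spans hemispheres. The canonical ordering makes the atlas fully
#' deterministic; `seed` is accepted for interface symmetry with the other
#' generators but does not influence the result.
#'
#' @param n_regions Even integer number of regions, at least 4.
#' @param seed Ignored (the atlas is deterministic); kept so that all
#'   generators share a common signature.
#' @return An object of class `region_atlas`: a list with `n_regions`,
#'   `hemisphere` (character vector, `"left"`/`"right"`), `homotopic_pair`
#'   (integer vector, 1-based partner index) and `region` (region names,
#'   `L001...`/`R001...`).
#' @examples
#' atlas <- generate_atlas(8)
#' atlas$homotopic_pair
#' @export
generate_atlas <- function(n_regions, seed = NULL) {
  if (length(n_regions) != 1L || !is.finite(n_regions) || n_regions < 4 ||
      n_regions %% 2 != 0) {
    stop("n_regions must be a single even integer >= 4", call. = FALSE)
  }
  n <- as.integer(n_regions)
  h <- n %/% 2L
  atlas <- structure(
    list(
      n_regions = n,
      hemisphere = rep(c("left", "right"), each = h),
      homotopic_pair = c(seq_len(h) + h, seq_len(h)),
      region = c(sprintf("L%03d", seq_len(h)), sprintf("R%03d", seq_len(h)))
    ),
    class = "region_atlas"
  )
  validate_atlas(atlas)
  atlas
}

validate_atlas <- function(atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  n <- atlas$n_regions
  p <- atlas$homotopic_pair
  if (length(p) != n || any(p[p] != seq_len(n)) || any(p == seq_len(n))) {
    stop("homotopic_pair must be a fixed-point-free involution", call. = FALSE)
  }
  if (any(atlas$hemisphere == atlas$hemisphere[p])) {
    stop("homotopic pairs must span hemispheres", call. = FALSE)
  }
  if (sum(atlas$hemisphere == "left") != n / 2) {
    stop("hemispheres must be balanced", call. = FALSE)
  }
  invisible(atlas)
}

#' @export
print.region_atlas <- function(x, ...) {
  cat("region_atlas:", x$n_regions, "regions,",
      x$n_regions / 2, "homotopic pairs\n")
  invisible(x)
}

# n x n logical matrix, TRUE where regions i and j lie in different hemispheres
interhemispheric_mask <- function(atlas) {
  outer(atlas$hemisphere, atlas$hemisphere, "!=")
}

# n x n logical matrix, TRUE on homotopic (mirror-pair) entries
homotopic_mask <- function(atlas) {
  n <- atlas$n_regions
  m <- matrix(FALSE, n, n)
  m[cbind(seq_len(n), atlas$homotopic_pair)] <- TRUE
  m
}
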