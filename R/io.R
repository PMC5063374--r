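#' Write / read an SC matrix as delimited text
#'
#' Tab-separated matrix with a header row and a first column of region names;
#' the atlas sidecar (region, hemisphere) is written next to it with suffix
#' `.atlas.tsv`. Region names round-trip byte-identically.
#'
#' @param sc An `sc_matrix`.
#' @param path Output file path (the sidecar gets `paste0(path, ".atlas.tsv")`).
#' @return `path`, invisibly.
#' @export
write_sc <- function(sc, path) {
  df <- data.frame(region = rownames(sc$weights), sc$weights,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- data.frame(region = sc$atlas$region,
                        hemisphere = sc$atlas$hemisphere)
  write.table(sidecar, paste0(path, ".atlas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_sc
#' @param threshold_applied Threshold recorded on the read matrix (default 0).
#' @return For `read_sc`: an `sc_matrix`.
#' @export
read_sc <- function(path, threshold_applied = 0) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  regions <- df[[1]]
  w <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(w) <- "double"
  side <- read.table(paste0(path, ".atlas.tsv"), sep = "\t", header = TRUE,
                     colClasses = "character")
  if (!identical(side$region, regions) || !identical(colnames(w), regions)) {
    stop("region names disagree between matrix and sidecar", call. = FALSE)
  }
  n <- length(regions)
  h <- n %/% 2L
  atlas <- structure(list(n_regions = n, hemisphere = side$hemisphere,
                          homotopic_pair = c(seq_len(h) + h, seq_len(h)),
                          region = regions),
                     class = "region_atlas")
  validate_atlas(atlas)
  rownames(w) <- NULL; colnames(w) <- NULL
  sc_matrix(w, atlas, threshold_applied = threshold_applied)
}

#' Write / read a BOLD run as delimited text
#'
#' Tab-separated regions x timepoints matrix with region-name row labels; the
#' sampling interval and GSR flag are stored in a `# tr=... gsr=...` comment
#' on the first line.
#'
#' @param bold A `bold_run`.
#' @param path Output file path.
#' @return `path`, invisibly; for `read_bold`, a `bold_run`.
#' @export
write_bold <- function(bold, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr=%.10g gsr=%d", bold$tr, as.integer(bold$gsr_applied)),
             con)
  rn <- rownames(bold$values)
  if (is.null(rn)) rn <- sprintf("R%03d", seq_len(nrow(bold$values)))
  write.table(data.frame(region = rn, bold$values, check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path) {
  header <- readLines(path, n = 1)
  tr <- as.numeric(sub(".*tr=([0-9.eE+-]+).*", "\\1", header))
  gsr <- sub(".*gsr=([01]).*", "\\1", header) == "1"
  df <- read.table(path, sep = "\t", header = TRUE, skip = 1,
                   check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  colnames(vals) <- NULL
  bold_run(vals, tr = tr, gsr_applied = gsr)
}

#' Write / read a connectivity vector as delimited text
#'
#' Two columns (pair/triplet id `"i-j"` or `"i-j-k"`, value) preceded by a
#' one-line header recording measure, region count, window size and the kNN
#' `k` where applicable.
#'
#' @param v A `connectivity_vector`.
#' @param path Output file path.
#' @param k Optional kNN neighbour count to record.
#' @return `path`, invisibly; for `read_connectivity`, a
#'   `connectivity_vector`.
#' @export
write_connectivity <- function(v, path, k = NA) {
  idx <- attr(v, "index")
  ws <- attr(v, "window_size")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# measure=%s n_regions=%d window_size=%s k=%s",
                     attr(v, "measure"), attr(v, "n_regions"),
                     if (is.null(ws)) "NA" else ws, k), con)
  ids <- apply(idx, 1, paste, collapse = "-")
  n_win <- length(v) / nrow(idx)
  ids <- rep(ids, times = n_win)
  write.table(data.frame(id = ids, value = as.numeric(v)), con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path) {
  header <- readLines(path, n = 1)
  get_field <- function(name) sub(sprintf(".*%s=([^ ]+).*", name), "\\1", header)
  measure <- get_field("measure")
  n_regions <- as.integer(get_field("n_regions"))
  ws <- get_field("window_size")
  df <- read.table(path, sep = "\t", header = TRUE, skip = 1)
  parts <- strsplit(df$id, "-", fixed = TRUE)
  width <- length(parts[[1]])
  n_idx <- if (measure == "dynFC") {
    sum(!duplicated(df$id))
  } else {
    nrow(df)
  }
  idx <- matrix(as.integer(unlist(parts[seq_len(n_idx)])), n_idx, width,
                byrow = TRUE)
  colnames(idx) <- if (width == 2) c("i", "j") else c("i", "j", "k")
  connectivity_vector(df$value, idx, measure = measure, n_regions = n_regions,
                      window_size = if (ws == "NA") NULL else as.integer(ws))
}

#' Serialize an analysis report to JSON
#'
#' @param report A list (e.g. from [run_experiment()] or a summarized
#'   `bootstrap_svd`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
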