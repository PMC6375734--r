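# Origin-centered heatmaps and metaprofiles. Rows are origins ordered by
# their normal replication time (t_rep); columns are fixed offsets from the
# origin midpoint. Masked cells (centromere overlap, chromosome-edge
# truncation) are NA and never contribute to averages.

#' Build an origin-centered heatmap matrix
#'
#' Extracts, for every origin, the stretch of track bins centred on the
#' origin's bin out to `window` bp on each side, and stacks them as rows
#' sorted by ascending t_rep (ties by chromosome order, then position).
#' Offsets that fall outside the chromosome are masked. The origin
#' midpoint's bin is the centre column, so there are
#' `2 * window / bin_width + 1` columns.
#'
#' @param track A normalized ChIP track or copy-number profile (any per-bin
#'   tibble with a `value` column and track attributes).
#' @param origins Origin tibble with `t_rep`.
#' @param window Half-window in bp (default 5000).
#' @return An `origin_heatmap`: list with `values` (matrix, one row per
#'   origin), `origins` (row metadata in row order), `offsets` (bp, bin
#'   centre relative to the origin), `window` and `bin_width`.
#' @export
build_heatmap <- function(track, origins, window = 5000) {
  bw <- track_bin_width(track)
  genome <- track_genome(track)
  missing <- setdiff(unique(as.character(origins$chrom)), genome$chrom)
  if (length(missing) > 0) {
    abort(paste0("origin chromosome missing from track: ",
                 paste(missing, collapse = ", ")))
  }
  n_off <- as.integer(window %/% bw)
  rel <- seq.int(-n_off, n_off)
  ord <- origins %>%
    mutate(chrom_rank = match(as.character(.data$chrom), genome$chrom)) %>%
    arrange(.data$t_rep, .data$chrom_rank, .data$pos) %>%
    select(-"chrom_rank") %>%
    mutate(origin_id = sprintf("%s:%d", .data$chrom, .data$pos))
  chrom_vals <- split(track$value, as.character(track$chrom))
  values <- matrix(NA_real_, nrow = nrow(ord), ncol = length(rel),
                   dimnames = list(ord$origin_id, NULL))
  for (i in seq_len(nrow(ord))) {
    vals <- chrom_vals[[as.character(ord$chrom[i])]]
    center <- ord$pos[i] %/% bw + 1L
    idx <- center + rel
    inside <- idx >= 1L & idx <= length(vals)
    values[i, inside] <- vals[idx[inside]]
  }
  structure(
    list(values = values, origins = ord, offsets = rel * bw,
         window = window, bin_width = bw),
    class = "origin_heatmap")
}

#' @export
print.origin_heatmap <- function(x, ...) {
  cat(sprintf(
    "# An origin-centered heatmap: %d origins x %d offsets (+/-%d bp, %d bp bins)\n",
    nrow(x$values), ncol(x$values), x$window, x$bin_width))
  invisible(x)
}

#' @export
tidy.origin_heatmap <- function(x, ...) {
  tibble(
    origin_id = rep(x$origins$origin_id, times = ncol(x$values)),
    t_rep = rep(x$origins$t_rep, times = ncol(x$values)),
    offset = rep(x$offsets, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' @export
glance.origin_heatmap <- function(x, ...) {
  tibble(n_origins = nrow(x$values), n_offsets = ncol(x$values),
         window = x$window, bin_width = x$bin_width,
         n_masked_cells = sum(is.na(x$values)))
}

#' Average signal profile across origins
#'
#' Masked-cell-aware column means of an origin-centered heatmap, with the
#' number of contributing origins per offset. An all-masked offset is
#' reported as masked (`NA`), not zero.
#'
#' @param hm An [build_heatmap()] result.
#' @return An `average_profile` tibble: `offset`, `value`, `n_contributing`.
#' @export
average_profile <- function(hm) {
  n_contributing <- colSums(!is.na(hm$values))
  value <- ifelse(n_contributing > 0, colMeans(hm$values, na.rm = TRUE),
                  NA_real_)
  structure(
    tibble(offset = hm$offsets, value = value,
           n_contributing = as.integer(n_contributing)),
    bin_width = hm$bin_width, window = hm$window,
    class = c("average_profile", class(tibble())))
}

#' Track the peak position of signal across timepoints
#'
#' For each profile in a time-ordered list, symmetrizes the signal about
#' the origin (forks move outward on both sides) and reports the offset
#' with the maximum symmetrized value. A flat profile has no defined peak
#' and is flagged.
#'
#' @param profiles A (optionally named) list of [average_profile()] results
#'   on identical offset grids.
#' @return A tibble with `timepoint`, `peak_offset` (bp, non-negative) and
#'   `flat`.
#' @export
track_signal_position <- function(profiles) {
  if (length(profiles) < 2) abort("need at least two timepoints")
  grids <- purrr::map(profiles, "offset")
  if (!all(purrr::map_lgl(grids, identical, grids[[1]]))) {
    abort("profiles are on mismatched offset grids")
  }
  labels <- names(profiles) %||% as.character(seq_along(profiles))
  purrr::map_dfr(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    d <- abs(p$offset)
    sym <- tapply(p$value, d, mean, na.rm = TRUE)
    dist <- as.numeric(names(sym))
    ok <- is.finite(sym)
    flat <- !any(ok) || diff(range(sym[ok])) == 0
    peak <- if (flat) NA_real_ else dist[ok][which.max(sym[ok])]
    tibble(timepoint = labels[i], peak_offset = peak, flat = flat)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a heatmap as TSV matrix plus row-order listing
#'
#' @param hm An origin heatmap.
#' @param path Output TSV path for the matrix (rows = origins in t_rep
#'   order, columns = offsets in bp).
#' @param row_order_path Output TSV for the row order (origin id, t_rep);
#'   default `path` with a `.rows.tsv` suffix.
#' @return The matrix path, invisibly.
#' @export
write_heatmap_tsv <- function(hm, path, row_order_path = paste0(path, ".rows.tsv")) {
  mat <- as_tibble(hm$values, .name_repair = ~ as.character(hm$offsets))
  mat <- dplyr::bind_cols(tibble(origin_id = hm$origins$origin_id), mat)
  readr::write_tsv(mat, path, progress = FALSE)
  readr::write_tsv(hm$origins[c("origin_id", "t_rep")], row_order_path,
                   progress = FALSE)
  invisible(path)
}
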