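#' Partition chromosomes into fixed genetic-length windows
#'
#' Divides each chromosome into consecutive windows of `window_cm`
#' centimorgans (default 2 cM) on the cumulative genetic map, starting at
#' the chromosome's first mapped position.  A trailing (telomeric) span
#' shorter than the window length is dropped; chromosomes with total map
#' below one window yield no windows.
#'
#' @param map A tibble with columns `chrom`, `bp`, `cm` (cumulative
#'   centimorgans per chromosome), as returned by [read_genetic_map()],
#'   or a single-chromosome [recomb_map()].
#' @param window_cm Window genetic length in centimorgans.
#' @return A tibble with `chrom`, `start_bp`, `end_bp`, `map_start`,
#'   `map_end` (Morgans) and `rr_mean` (cM/Mb over the window).
#' @examples
#' m <- tibble::tibble(chrom = "1", bp = c(0, 1e7), cm = c(0, 10))
#' partition_windows(m)   # 5 windows of 2 Mb at 1 cM/Mb
#' @export
partition_windows <- function(map, window_cm = 2) {
  if (inherits(map, "recomb_map"))
    map <- tibble::tibble(chrom = "1", bp = map$bp, cm = 100 * map$morgans)
  stopifnot(all(c("chrom", "bp", "cm") %in% names(map)), window_cm > 0)
  purrr::map_dfr(split(map, map$chrom), function(mm) {
    mm <- dplyr::arrange(mm, .data$bp)
    if (is.unsorted(mm$cm))
      stop("cumulative cM must be non-decreasing", call. = FALSE)
    total <- mm$cm[nrow(mm)] - mm$cm[1]
    k <- floor(total / window_cm + 1e-9)
    if (k < 1) return(tibble::tibble())
    edges_cm <- mm$cm[1] + window_cm * (0:k)
    edges_bp <- inv_map_cm(mm, edges_cm)
    tibble::tibble(
      chrom = mm$chrom[1],
      start_bp = edges_bp[-(k + 1)], end_bp = edges_bp[-1],
      map_start = edges_cm[-(k + 1)] / 100, map_end = edges_cm[-1] / 100,
      rr_mean = window_cm / ((edges_bp[-1] - edges_bp[-(k + 1)]) / 1e6))
  })
}

# invert a per-chromosome cumulative map (cm as function of bp); flat
# stretches return their leftmost bp
inv_map_cm <- function(mm, cm_query) {
  vapply(cm_query, function(q) {
    k <- findInterval(q, mm$cm, rightmost.closed = TRUE)
    k <- max(1L, min(k, nrow(mm) - 1L))
    span <- mm$cm[k + 1] - mm$cm[k]
    if (span <= 0) return(mm$bp[k])
    mm$bp[k] + (q - mm$cm[k]) / span * (mm$bp[k + 1] - mm$bp[k])
  }, numeric(1))
}

#' Per-window diversity statistics and regional Ne
#'
#' For each window computes:
#' * `pi` - sum over segregating sites of `2 p (1-p) n_h/(n_h - 1)`
#'   divided by the window's bp length (monomorphic sites contribute 0);
#' * `P` - proportion of polymorphic sites (S / bp length);
#' * `maf_mean` - mean minor allele frequency over the window's SNPs;
#' * `rr_mean` - window genetic span over physical span, in cM/Mb;
#' * `ne_ld` - the constant-size regional LD estimate ([regional_ne()]),
#'   with its available pair count `n_pairs` and `enough_pairs` flag;
#' * the window means/sums of any annotation tracks supplied.
#'
#' @param sample A [hap_sample()] (phased or not) covering the windows.
#' @param windows Output of [partition_windows()].
#' @param tracks Optional annotation tibble with one row per window
#'   (matched by `chrom` + `start_bp`) holding extra columns such as
#'   `b_mean`, `lof_count`, `missense_count`, `gene_density`; or a
#'   BED-like per-feature tibble from [read_tracks()], aggregated by
#'   window midpoint membership.
#' @param min_snps Windows with fewer SNPs than this get `NA` statistics.
#' @param ... Passed to [regional_ne()].
#' @return `windows` with the statistic columns appended.
#' @export
window_stats <- function(sample, windows, tracks = NULL, min_snps = 2, ...) {
  stopifnot(inherits(sample, "hap_sample"), is.data.frame(windows))
  nh <- nrow(sample$matrix)
  p_all <- allele_freq(sample)
  stats <- purrr::pmap_dfr(
    windows[c("chrom", "start_bp", "end_bp")],
    function(chrom, start_bp, end_bp) {
      j <- which(sample$chrom == chrom &
                   sample$positions_bp >= start_bp &
                   sample$positions_bp < end_bp)
      len <- end_bp - start_bp
      p <- p_all[j]
      poly <- p > 0 & p < 1
      corr <- if (sample$phased) nh / (nh - 1) else
        (2 * nh) / (2 * nh - 1)
      pi <- sum(2 * p[poly] * (1 - p[poly])) * corr / len
      base <- tibble::tibble(
        n_snps = sum(poly), pi = pi, P = sum(poly) / len,
        maf_mean = if (any(poly)) mean(pmin(p[poly], 1 - p[poly]))
                   else NA_real_,
        ne_ld = NA_real_, n_pairs = 0L, enough_pairs = FALSE)
      if (length(j) < max(min_snps, 2)) return(base)
      sub <- hap_sample(sample$matrix[, j, drop = FALSE],
                        sample$positions_bp[j], sample$map_morgans[j],
                        sample$chrom[j], phased = sample$phased,
                        drop_monomorphic = TRUE)
      ne <- regional_ne(sub, ...)
      base$ne_ld <- ne$ne_hat
      base$n_pairs <- ne$n_pairs
      base$enough_pairs <- ne$enough_pairs
      base
    })
  out <- dplyr::bind_cols(windows, stats)
  if (!is.null(tracks)) out <- join_tracks(out, tracks)
  out
}

# attach per-window annotation values; features (with their own
# start/end) are assigned to the window containing their midpoint
join_tracks <- function(windows, tracks) {
  stopifnot(is.data.frame(tracks))
  if ("value" %in% names(tracks) && "name" %in% names(tracks)) {
    # BED-like long format: chrom, start, end, name, value
    mid <- (tracks$start + tracks$end) / 2
    tracks$._w <- window_index(windows, tracks$chrom, mid)
    agg <- tracks |>
      dplyr::filter(!is.na(.data$._w)) |>
      dplyr::group_by(.data$._w, .data$name) |>
      dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "name", values_from = "value")
    out <- windows
    out$._w <- seq_len(nrow(out))
    out <- dplyr::left_join(out, agg, by = "._w")
    out$._w <- NULL
    return(out)
  }
  dplyr::left_join(windows, tracks, by = c("chrom", "start_bp"))
}

window_index <- function(windows, chrom, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (k in seq_len(nrow(windows))) {
    hit <- chrom == windows$chrom[k] & pos >= windows$start_bp[k] &
      pos < windows$end_bp[k]
    idx[hit] <- k
  }
  idx
}

#' Filter windows by LD-estimation quality rules
#'
#' Keeps windows with strictly more than `min_pairs` SNP pairs in the
#' regional c-range and a regional Ne estimate in `(0, ne_max]`
#' (default 100,000); negative, zero, missing or extreme estimates are
#' excluded.  Per-rule exclusion tallies are attached as attribute
#' `"exclusions"` and always satisfy kept + excluded = total.
#'
#' @param stats Output of [window_stats()].
#' @param min_pairs Pair-count threshold (strict `>`).
#' @param ne_max Upper bound on `ne_ld` (strict `>` excludes).
#' @return The filtered tibble.
#' @export
filter_windows <- function(stats, min_pairs = 250000, ne_max = 1e5) {
  stopifnot(is.data.frame(stats),
            all(c("n_pairs", "ne_ld") %in% names(stats)))
  few  <- !(stats$n_pairs > min_pairs)
  bad  <- !few & (is.na(stats$ne_ld) | stats$ne_ld <= 0)
  big  <- !few & !bad & stats$ne_ld > ne_max
  keep <- !(few | bad | big)
  out <- stats[keep, , drop = FALSE]
  attr(out, "exclusions") <- tibble::tibble(
    rule = c("insufficient_pairs", "nonpositive_ne", "ne_above_max",
             "kept"),
    n = c(sum(few), sum(bad), sum(big), sum(keep)))
  out
}

#' Spearman correlations between window variables
#'
#' Rank correlation (average ranks on ties) with a two-sided p-value from
#' the t-approximation on `n - 2` degrees of freedom, for each requested
#' variable pair across windows.  Pairs where either variable is constant
#' or fewer than `min_windows` complete observations exist are reported
#' with `NA` and a reason.
#'
#' @param stats A window-statistics tibble (normally after
#'   [filter_windows()]).
#' @param variable_pairs A list of length-2 character vectors; by default
#'   `pi` and `ne_ld` against every other numeric variable present among
#'   `rr_mean`, `b_mean`, `P`, `maf_mean`, `lof_count`,
#'   `missense_count`, `gene_density`, plus the full pairwise matrix if
#'   `all_pairs = TRUE`.
#' @param all_pairs Also compute every pairwise combination of the focal
#'   variables.
#' @param min_windows Minimum complete observations per pair.
#' @return A tibble of class `scan_correlations` with `var_x`, `var_y`,
#'   `rho`, `p_value`, `n_windows`, `reason`.
#' @export
correlate_windows <- function(stats, variable_pairs = NULL,
                              all_pairs = FALSE, min_windows = 5) {
  stopifnot(is.data.frame(stats))
  focal <- intersect(c("pi", "ne_ld", "rr_mean", "b_mean", "P", "maf_mean",
                       "lof_count", "missense_count", "gene_density"),
                     names(stats))
  if (is.null(variable_pairs)) {
    ys <- setdiff(focal, c("pi", "ne_ld"))
    variable_pairs <- c(
      lapply(ys, function(v) c("pi", v)),
      lapply(ys, function(v) c("ne_ld", v)),
      list(c("pi", "ne_ld")))
    if (all_pairs)
      variable_pairs <- unique(c(variable_pairs,
        utils::combn(focal, 2, simplify = FALSE)))
  }
  out <- purrr::map_dfr(variable_pairs, function(vp) {
    x <- stats[[vp[1]]]; y <- stats[[vp[2]]]
    ok <- is.finite(x) & is.finite(y)
    base <- tibble::tibble(var_x = vp[1], var_y = vp[2],
                           rho = NA_real_, p_value = NA_real_,
                           n_windows = sum(ok), reason = NA_character_)
    if (sum(ok) < min_windows) {
      base$reason <- "too few windows"
    } else if (length(unique(x[ok])) < 2 || length(unique(y[ok])) < 2) {
      base$reason <- "constant variable"
    } else {
      ct <- suppressWarnings(
        cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      base$rho <- unname(ct$estimate)
      base$p_value <- ct$p.value
    }
    base
  })
  class(out) <- c("scan_correlations", class(out))
  out
}

#' @rdname correlate_windows
#' @param object A `scan_correlations` tibble.
#' @param ... Unused.
#' @export
autoplot.scan_correlations <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$rho)) |>
    dplyr::mutate(pair = paste(.data$var_x, "~", .data$var_y),
                  sig = dplyr::case_when(.data$p_value < 0.001 ~ "***",
                                         .data$p_value < 0.05 ~ "*",
                                         TRUE ~ ""))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pair, y = .data$rho,
                                  fill = .data$var_x)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig), vjust = 0) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Spearman rho") +
    ggplot2::theme_minimal()
}

#' Windowed genome scan
#'
#' Convenience wrapper: partitions the map into windows, computes window
#' statistics, applies the exclusion rules and correlates the surviving
#' windows.
#'
#' @inheritParams window_stats
#' @param map Genetic-map tibble (`chrom`, `bp`, `cm`).
#' @param window_cm Window size in cM.
#' @param min_pairs,ne_max Filter thresholds (see [filter_windows()]).
#' @param ... Passed to [regional_ne()] via [window_stats()].
#' @return A list of class `genome_scan` with `windows` (all, with
#'   stats), `kept` (post-filter), `correlations` and `exclusions`.
#' @export
scan_genome <- function(sample, map, tracks = NULL, window_cm = 2,
                        min_pairs = 250000, ne_max = 1e5, ...) {
  win <- partition_windows(map, window_cm)
  if (nrow(win) == 0) stop("no chromosome provides a full window",
                           call. = FALSE)
  st <- window_stats(sample, win, tracks = tracks, ...)
  kept <- filter_windows(st, min_pairs = min_pairs, ne_max = ne_max)
  corr <- if (nrow(kept) >= 5) correlate_windows(kept) else NULL
  structure(list(windows = st, kept = kept, correlations = corr,
                 exclusions = attr(kept, "exclusions")),
            class = "genome_scan")
}

#' @export
print.genome_scan <- function(x, ...) {
  cat(sprintf("<genome_scan> %d windows, %d kept after filtering\n",
              nrow(x$windows), nrow(x$kept)))
  if (!is.null(x$correlations)) print(tibble::as_tibble(x$correlations))
  invisible(x)
}
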