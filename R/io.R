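#' Write a haplotype sample as minimal VCF
#'
#' Emits a spec-conformant minimal VCF 4.2: biallelic SNPs only, GT
#' field only, phased ("|") for haplotype samples and unphased ("/") for
#' dosage samples.  Internal 0-based positions become 1-based POS.  The
#' REF/ALT alleles are synthetic placeholders (A/C).
#'
#' @param sample A [hap_sample()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sample, path) {
  stopifnot(inherits(sample, "hap_sample"))
  m <- sample$matrix
  n_ind <- sample$n_ind
  if (sample$phased) {
    a1 <- m[seq(1, nrow(m), 2), , drop = FALSE]
    a2 <- m[seq(2, nrow(m), 2), , drop = FALSE]
    gt <- matrix(paste0(a1, "|", a2), nrow = n_ind)
  } else {
    gt <- matrix(c("0/0", "0/1", "1/1")[m + 1], nrow = n_ind)
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ldnescan",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##contig=<ID=", unique(sample$chrom), ">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT",
                   sprintf("ind%03d", seq_len(n_ind))), collapse = "\t"))
  body <- paste(sample$chrom, sample$positions_bp + 1,
                sprintf("snp%d", seq_along(sample$chrom)),
                "A", "C", ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF into a haplotype sample
#'
#' Reads biallelic SNP records with a GT field (via `vcfR`).  Phased
#' records ("|") are loaded as haplotypes; unphased ("/") as genotype
#' dosages for the composite-LD mode.  Mixed phasing is treated as
#' unphased.  Multi-allelic or GT-less records are skipped with a count
#' (attribute `"n_skipped"`), or rejected in `strict` mode.  Map
#' positions are interpolated from `map` when given, else set to zero.
#'
#' @param path VCF path.
#' @param map Optional genetic-map tibble (`chrom`, `bp`, `cm`) used to
#'   assign per-site Morgan positions.
#' @param strict Error on skipped records instead of counting them.
#' @return A [hap_sample()] with attribute `n_skipped`.
#' @export
read_vcf <- function(path, map = NULL, strict = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt_raw <- v@gt
  ok <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "." &
    grepl("GT", gt_raw[, "FORMAT"])
  n_skipped <- sum(!ok)
  if (n_skipped > 0 && strict)
    stop(n_skipped, " record(s) are multi-allelic or lack GT", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[ok, , drop = FALSE]
  chrom <- fix[ok, "CHROM"]
  pos <- as.numeric(fix[ok, "POS"]) - 1   # to 0-based
  phased <- all(grepl("|", gt, fixed = TRUE))
  n_ind <- ncol(gt)
  if (phased) {
    sp <- strsplit(as.vector(gt), "|", fixed = TRUE)
    a <- matrix(as.integer(unlist(sp)), nrow = 2)
    m <- matrix(0L, nrow = 2 * n_ind, ncol = nrow(gt))
    for (j in seq_len(n_ind)) {
      cols <- (j - 1) * nrow(gt) + seq_len(nrow(gt))
      m[2 * j - 1, ] <- a[1, cols]
      m[2 * j, ] <- a[2, cols]
    }
  } else {
    dose <- matrix(vapply(strsplit(as.vector(gt), "[/|]"),
                          function(x) sum(as.integer(x)), integer(1)),
                   nrow = nrow(gt))
    m <- t(dose)
  }
  mm <- if (is.null(map)) rep(0, length(pos)) else
    map_morgans_at(map, chrom, pos)
  out <- hap_sample(m, pos, mm, chrom, phased = phased,
                    drop_monomorphic = TRUE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a genetic map sidecar
#'
#' Three whitespace-separated, headered columns: chromosome, physical
#' position (bp) and cumulative genetic position (cM).  Positions must be
#' sorted and the cumulative map non-decreasing within each chromosome.
#'
#' @param path Map file path.
#' @return A tibble with columns `chrom`, `bp`, `cm`.
#' @export
read_genetic_map <- function(path) {
  m <- readr::read_table(path, col_types = readr::cols(
    chrom = readr::col_character(), bp = readr::col_double(),
    cm = readr::col_double()))
  for (ch in unique(m$chrom)) {
    sub <- m[m$chrom == ch, ]
    if (is.unsorted(sub$bp))
      stop("map positions must be sorted within chromosome ", ch,
           call. = FALSE)
    if (is.unsorted(sub$cm))
      stop("cumulative cM decreases within chromosome ", ch, call. = FALSE)
  }
  m
}

#' @rdname read_genetic_map
#' @param map Map tibble (`chrom`, `bp`, `cm`).
#' @param path Output path.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(all(c("chrom", "bp", "cm") %in% names(map)))
  readr::write_tsv(map[c("chrom", "bp", "cm")], path)
  invisible(path)
}

# interpolate cumulative Morgans at (chrom, bp); linear between anchors,
# constant-rate extrapolation at the nearest segment outside them
map_morgans_at <- function(map, chrom, bp) {
  out <- numeric(length(bp))
  for (ch in unique(chrom)) {
    sub <- map[map$chrom == ch, ]
    j <- chrom == ch
    if (nrow(sub) < 2) { out[j] <- 0; next }
    cm <- approx(sub$bp, sub$cm, xout = bp[j], rule = 2,
                 ties = "ordered")$y
    # extrapolate beyond the anchors at the flanking segment's rate
    below <- bp[j] < sub$bp[1]
    above <- bp[j] > sub$bp[nrow(sub)]
    if (any(below)) {
      r <- (sub$cm[2] - sub$cm[1]) / (sub$bp[2] - sub$bp[1])
      cm[below] <- sub$cm[1] + (bp[j][below] - sub$bp[1]) * r
    }
    if (any(above)) {
      k <- nrow(sub)
      r <- (sub$cm[k] - sub$cm[k - 1]) / (sub$bp[k] - sub$bp[k - 1])
      cm[above] <- sub$cm[k] + (bp[j][above] - sub$bp[k]) * r
    }
    out[j] <- cm / 100
  }
  out
}

#' Read BED-like annotation tracks
#'
#' Headered TSV with columns `chrom`, `start`, `end`, `name`, `value`;
#' one row per feature per track name (long format).
#'
#' @param path Track file path.
#' @return A tibble.
#' @export
read_tracks <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), name = readr::col_character(),
    value = readr::col_double()))
}
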