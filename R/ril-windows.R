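# Genomic-window derivation calls for recombinant inbred lines.
#
# Polymorphism counts against the reference (Tak-1) are tallied for Tak-2,
# Rit-1 and Rit-2 in fixed windows; windows with a significant count
# (strictly more than 100 per 100 kb, proportionally scaled) are flagged,
# and the intersection pattern of flags classifies each autosomal window as
# derived from TAK1, TAK2 or SHARED between the parents.

#' Count per-line polymorphisms in fixed windows
#'
#' Windows are half-open `[ (k-1) w, k w )` tiles in position coordinates;
#' a variant exactly at a window boundary belongs to the upper window. The
#' last window is truncated at the chromosome end (a variant exactly at the
#' end stays in it), so window widths always sum to the chromosome length.
#'
#' @param variants data frame with columns `chrom`, `pos` (1-based),
#'   `line`.
#' @param window_size window width in bp (e.g. 1e5 or 1e6).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param lines line names to tabulate (columns in the result).
#' @return tibble: chrom, start, end (half-open bounds), width, one count
#'   column per line, and `intersection` (positions present in all lines).
#' @export
count_window_polymorphisms <- function(variants, window_size, chrom_lengths,
                                       lines = c("tak2", "rit1", "rit2")) {
  stopifnot(window_size > 0, !is.null(names(chrom_lengths)))
  v <- dplyr::as_tibble(variants)
  if (!all(c("chrom", "pos", "line") %in% names(v))) {
    stop("variants need columns chrom, pos, line", call. = FALSE)
  }
  bad_chrom <- !v$chrom %in% names(chrom_lengths)
  if (any(bad_chrom)) {
    stop("variant on unknown chromosome: ",
         paste(utils::head(unique(v$chrom[bad_chrom])), collapse = ", "),
         call. = FALSE)
  }
  out_of_range <- v$pos < 1 | v$pos > chrom_lengths[v$chrom]
  if (any(out_of_range)) {
    i <- which(out_of_range)[1]
    stop(sprintf("variant position out of range: %s:%d (line %s)",
                 v$chrom[i], v$pos[i], v$line[i]), call. = FALSE)
  }

  res <- list()
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    n_win <- max(1L, as.integer(ceiling(L / window_size)))
    start <- (seq_len(n_win) - 1) * window_size
    end <- pmin(seq_len(n_win) * window_size, L)
    vc <- v[v$chrom == chrom, ]
    idx <- pmin(vc$pos %/% window_size + 1L, n_win)
    counts <- sapply(lines, function(ln) {
      tabulate(idx[vc$line == ln], nbins = n_win)
    })
    if (n_win == 1L) counts <- matrix(counts, nrow = 1,
                                      dimnames = list(NULL, lines))
    # three-way intersection: identical positions present in every line
    inter <- tabulate(integer(0), nbins = n_win)
    if (nrow(vc)) {
      pos_by_line <- lapply(lines, function(ln) unique(vc$pos[vc$line == ln]))
      common <- Reduce(intersect, pos_by_line)
      if (length(common)) {
        inter <- tabulate(pmin(common %/% window_size + 1L, n_win), nbins = n_win)
      }
    }
    tab <- tibble::tibble(chrom = chrom, start = start, end = end,
                          width = end - start)
    for (ln in lines) tab[[ln]] <- counts[, ln]
    tab$intersection <- inter
    res[[chrom]] <- tab
  }
  out <- dplyr::bind_rows(res)
  attr(out, "window_size") <- window_size
  out
}

#' Flag windows with a significant polymorphism count
#'
#' A window is significant for a line when its count strictly exceeds the
#' threshold scaled to the window width: more than 100 polymorphisms per
#' 100 kb (equivalently 1,000 per 1,000 kb); truncated terminal windows
#' scale the threshold by their width fraction.
#'
#' @param counts output of [count_window_polymorphisms()].
#' @param threshold_per_100kb count threshold per 100 kb (default 100).
#' @param lines line columns to flag.
#' @return `counts` with one logical `sig_<line>` column per line.
#' @export
flag_significant <- function(counts, threshold_per_100kb = 100,
                             lines = c("tak2", "rit1", "rit2")) {
  thr <- threshold_per_100kb * counts$width / 1e5
  for (ln in lines) {
    counts[[paste0("sig_", ln)]] <- counts[[ln]] > thr
  }
  counts
}

#' Classify window derivation from significance flags
#'
#' No significant Tak-1/Tak-2 polymorphism density means the parents share
#' the region (SHARED). Where Tak-2 differs from Tak-1, the RIL genomes
#' tell which parent the region came from: a significant count in Rit-1 or
#' Rit-2 means the RILs carry the Tak-2 haplotype (TAK2); otherwise they
#' match the Tak-1 reference (TAK1).
#'
#' @param flags output of [flag_significant()].
#' @param sex_chroms chromosome names excluded from the autosomal calls
#'   (U/V sex chromosomes).
#' @return tibble of autosomal windows with a `call` column in
#'   \{SHARED, TAK1, TAK2\}; excluded sex-chromosome windows are reported
#'   via a message.
#' @export
classify_derivation <- function(flags, sex_chroms = c("chrU", "chrV", "U", "V")) {
  sex <- flags$chrom %in% sex_chroms
  if (any(sex)) {
    message(sprintf("excluding %d sex-chromosome window(s): %s",
                    sum(sex), paste(unique(flags$chrom[sex]), collapse = ", ")))
  }
  df <- flags[!sex, , drop = FALSE]
  df$call <- ifelse(!df$sig_tak2, "SHARED",
                    ifelse(df$sig_rit1 | df$sig_rit2, "TAK2", "TAK1"))
  df
}

#' Length-weighted derivation fractions
#'
#' @param calls output of [classify_derivation()].
#' @param chrom_lengths optional named lengths of the autosomes; when
#'   given, coverage is checked and gaps raise an error.
#' @return tibble with call, total width and fraction (fractions sum to 1).
#' @export
summarize_derivation <- function(calls, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) {
    for (chrom in names(chrom_lengths)) {
      w <- calls[calls$chrom == chrom, ]
      covered <- sum(w$width)
      if (abs(covered - chrom_lengths[[chrom]]) > 1e-6) {
        stop(sprintf("coverage gap on %s: windows cover %g of %g bp",
                     chrom, covered, chrom_lengths[[chrom]]), call. = FALSE)
      }
    }
  }
  tot <- sum(calls$width)
  agg <- dplyr::summarise(dplyr::group_by(calls, .data$call),
                          width = sum(.data$width), .groups = "drop")
  agg$fraction <- agg$width / tot
  dplyr::arrange(agg, dplyr::desc(.data$fraction))
}

#' Write derivation calls as a BED-like track
#'
#' @param calls output of [classify_derivation()].
#' @param path output TSV path (chrom, start, end, call).
#' @return invisibly, the written tibble.
#' @export
write_derivation_track <- function(calls, path) {
  track <- calls[, c("chrom", "start", "end", "call")]
  readr::write_tsv(track, path, col_names = FALSE)
  invisible(track)
}

#' Read a variant table (TSV or minimal VCF)
#'
#' TSV inputs need columns chrom, pos, line. VCF inputs use CHROM and POS
#' only; the line must then be supplied.
#'
#' @param path input file.
#' @param line line name for VCF input.
#' @return tibble with chrom, pos, line.
#' @export
read_variants <- function(path, line = NULL) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "##fileformat=VCF") || grepl("\\.vcf$", path)) {
    lines_raw <- readLines(path)
    body <- lines_raw[!startsWith(lines_raw, "#")]
    if (is.null(line)) stop("supply `line` for VCF input", call. = FALSE)
    parts <- strsplit(body, "\t")
    tibble::tibble(
      chrom = vapply(parts, `[[`, "", 1),
      pos = as.numeric(vapply(parts, `[[`, "", 2)),
      line = line
    )
  } else {
    readr::read_tsv(path, show_col_types = FALSE)
  }
}

#' Simulate a RIL genome with planted window derivations
#'
#' Generates per-line variant positions whose window counts sit well away
#' from the significance threshold, for testing the derivation logic:
#' SHARED windows get sparse counts in every line, TAK2 windows dense
#' counts in Tak-2, Rit-1 and Rit-2 (with a common core realizing the
#' intersection), TAK1 windows dense counts in Tak-2 only.
#'
#' @param plan tibble with columns chrom, window (1-based index), call.
#' @param window_size window width in bp.
#' @param chrom_lengths named chromosome lengths.
#' @param seed RNG seed.
#' @param dense,sparse expected counts (per full window) for significant
#'   and non-significant windows; defaults are 3x and 0.1x the threshold.
#' @return tibble with chrom, pos, line.
#' @export
simulate_ril_variants <- function(plan, window_size, chrom_lengths, seed = 1,
                                  dense = 3, sparse = 0.1) {
  thr <- 100 * window_size / 1e5
  out <- list()
  with_private_rng(seed, {
    for (i in seq_len(nrow(plan))) {
      chrom <- plan$chrom[i]; k <- plan$window[i]; call <- plan$call[i]
      L <- chrom_lengths[[chrom]]
      lo <- (k - 1) * window_size
      hi <- min(k * window_size, L)
      w_frac <- (hi - lo) / window_size
      draw_pos <- function(n) {
        n <- max(n, 0)
        unique(floor(stats::runif(n, max(lo, 1), hi)))
      }
      n_dense <- round(dense * thr * w_frac)
      n_sparse <- round(sparse * thr * w_frac)
      recs <- switch(call,
        SHARED = {
          lapply(c("tak2", "rit1", "rit2"), function(ln)
            tibble::tibble(chrom = chrom, pos = draw_pos(n_sparse), line = ln))
        },
        TAK2 = {
          core <- draw_pos(n_dense)
          lapply(c("tak2", "rit1", "rit2"), function(ln)
            tibble::tibble(chrom = chrom,
                           pos = unique(c(core, draw_pos(round(n_dense * 0.2)))),
                           line = ln))
        },
        TAK1 = {
          c(list(tibble::tibble(chrom = chrom, pos = draw_pos(n_dense),
                                line = "tak2")),
            lapply(c("rit1", "rit2"), function(ln)
              tibble::tibble(chrom = chrom, pos = draw_pos(n_sparse), line = ln)))
        },
        stop("unknown call in plan: ", call)
      )
      out[[length(out) + 1L]] <- dplyr::bind_rows(recs)
    }
  })
  dplyr::bind_rows(out)
}
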