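# Quantification of transgenic-rescue fertility assays: per-line brood
# summaries, genotype-level rescue fractions relative to wild-type transgene
# lines, rescue classification and the single/double-mutant compensation
# test.

#' Per-line brood summary
#'
#' Mean, standard error of the mean (sample SD over sqrt(n)) and worm count
#' for one transgenic line's per-worm live-progeny totals.
#'
#' @param counts Non-negative integer vector, one total brood per worm.
#' @return List with `mean`, `sem`, `n` and `sem_undefined` (TRUE when n = 1,
#'   where the SEM is reported as 0 with a flag rather than NA).
#' @examples
#' line_summary(c(39, 45, 33))
#' @export
line_summary <- function(counts) {
  if (length(counts) == 0L) stop("empty count vector", call. = FALSE)
  if (any(counts < 0)) stop("negative brood counts", call. = FALSE)
  n <- length(counts)
  m <- mean(counts)
  if (n == 1L) {
    list(mean = m, sem = 0, n = 1L, sem_undefined = TRUE)
  } else {
    list(mean = m, sem = stats::sd(counts) / sqrt(n), n = n,
         sem_undefined = FALSE)
  }
}

#' Format a brood summary the way rescue tables print it
#'
#' Means in (0, 1) render as `"<1"`; the numeric value is retained
#' internally.
#'
#' @param mean,sem Summary statistics.
#' @return Character scalar like `"39 ± 6"`.
#' @export
format_progeny <- function(mean, sem) {
  if (mean == 0) return("0")
  if (mean < 1) return("<1")
  sprintf("%.0f ± %.2g", mean, sem)
}

#' Transgenic rescue line
#'
#' One independently derived transgenic line: raw per-worm counts, or the
#' printed summary (mean, SEM, n) when only table values are available.  A
#' printed `"<1"` entry is ingested as mean 0.5 with `censored_lt1 = TRUE`.
#'
#' @param transgene_id Transgene/array identifier (e.g. "xyEx186").
#' @param genotype Genotype label of the construct (e.g. "C681A").
#' @param counts Optional per-worm brood counts.
#' @param mean,sem,n Optional printed summary (required when `counts` is
#'   absent); when both are given the summary must match the counts.
#' @param control_counts Optional broods of non-transgenic homozygote
#'   siblings, used by [recombinant_filter()].
#' @param censored_lt1 Whether the mean came from a `"<1"` table cell.
#' @return Object of class `rescue_line`.
#' @export
rescue_line <- function(transgene_id, genotype, counts = NULL,
                        mean = NULL, sem = NULL, n = NULL,
                        control_counts = NULL, censored_lt1 = FALSE) {
  if (!is.null(counts)) {
    s <- line_summary(counts)
    if (!is.null(mean) && abs(mean - s$mean) > 1e-8)
      stop("supplied mean disagrees with counts", call. = FALSE)
    if (!is.null(sem) && !s$sem_undefined && abs(sem - s$sem) > 1e-8)
      stop("supplied sem disagrees with counts", call. = FALSE)
    mean <- s$mean; sem <- s$sem; n <- s$n
  } else {
    if (is.null(mean) || is.null(n))
      stop("need counts, or mean and n", call. = FALSE)
    if (is.null(sem)) sem <- 0
  }
  stopifnot(n >= 1L, mean >= 0, sem >= 0)
  structure(list(transgene_id = transgene_id, genotype = genotype,
                 counts = counts, mean = mean, sem = sem, n = as.integer(n),
                 control_counts = control_counts,
                 censored_lt1 = isTRUE(censored_lt1)),
            class = "rescue_line")
}

#' @export
print.rescue_line <- function(x, ...) {
  cat(sprintf("<rescue_line> %s %s: %s (n = %d)\n", x$transgene_id,
              x$genotype, format_progeny(x$mean, x$sem), x$n))
  invisible(x)
}

line_means <- function(lines) vapply(lines, `[[`, 0, "mean")
line_ns <- function(lines) vapply(lines, `[[`, 0L, "n")

grand_mean <- function(lines, weighting = c("unweighted", "n-weighted")) {
  weighting <- match.arg(weighting)
  m <- line_means(lines)
  if (weighting == "unweighted") mean(m)
  else stats::weighted.mean(m, line_ns(lines))
}

#' Classify a rescue fraction
#'
#' Default thresholds: below 0.10 null-like; 0.10 to 0.80 partial
#' (boundaries inclusive upward); above 0.80 full.
#'
#' @param fraction Rescue fraction (>= 0).
#' @param thresholds Named vector `c(null_like =, full =)`.
#' @return `"null-like"`, `"partial"` or `"full"`.
#' @export
classify_rescue <- function(fraction,
                            thresholds = c(null_like = 0.10, full = 0.80)) {
  if (any(fraction < 0)) stop("negative rescue fraction", call. = FALSE)
  ifelse(fraction < thresholds[["null_like"]], "null-like",
         ifelse(fraction <= thresholds[["full"]], "partial", "full"))
}

#' Genotype-level rescue relative to a reference
#'
#' Aggregates line means into a grand mean per genotype (unweighted
#' mean-of-line-means by default, so each independently derived array counts
#' once; n-weighted mode pools by worm count) and expresses the mutant grand
#' mean as a fraction of the reference (wild-type transgene) grand mean.
#'
#' @param lines List of [rescue_line()] objects for one genotype.
#' @param reference List of [rescue_line()] objects for the reference
#'   genotype.
#' @param weighting `"unweighted"` or `"n-weighted"`.
#' @param thresholds Passed to [classify_rescue()].
#' @return Object of class `genotype_summary` with `genotype_label`,
#'   `line_means`, `grand_mean`, `rescue_fraction` and `classification`.
#' @examples
#' c681a <- list(rescue_line("xyEx186", "C681A", mean = 39, sem = 6, n = 10),
#'               rescue_line("xyEx187", "C681A", mean = 51, sem = 11, n = 7),
#'               rescue_line("xyEx188", "C681A", mean = 63, sem = 12, n = 5))
#' wt <- list(rescue_line("ebEx498", "wild type", mean = 92, sem = 16, n = 11),
#'            rescue_line("xyEx175", "wild type", mean = 123, sem = 15, n = 10),
#'            rescue_line("xyEx177", "wild type", mean = 115, sem = 17, n = 11))
#' genotype_rescue(c681a, wt)
#' @export
genotype_rescue <- function(lines, reference,
                            weighting = c("unweighted", "n-weighted"),
                            thresholds = c(null_like = 0.10, full = 0.80)) {
  weighting <- match.arg(weighting)
  if (length(lines) == 0L || length(reference) == 0L)
    stop("empty line list", call. = FALSE)
  gm <- grand_mean(lines, weighting)
  ref <- grand_mean(reference, weighting)
  if (ref <= 0) stop("reference grand mean must be positive", call. = FALSE)
  frac <- gm / ref
  structure(list(genotype_label = lines[[1L]]$genotype,
                 line_means = line_means(lines),
                 grand_mean = gm,
                 reference_label = reference[[1L]]$genotype,
                 reference_grand_mean = ref,
                 rescue_fraction = frac,
                 classification = classify_rescue(frac, thresholds),
                 weighting = weighting),
            class = "genotype_summary")
}

#' @export
print.genotype_summary <- function(x, ...) {
  cat(sprintf(
    "<genotype_summary> %s: grand mean %.1f (%d lines), %.1f%% of %s -> %s\n",
    x$genotype_label, x$grand_mean, length(x$line_means),
    100 * x$rescue_fraction, x$reference_label, x$classification))
  invisible(x)
}

#' Single/double-mutant compensation test
#'
#' Decides between a compensation scenario (a dispensable residue rescues the
#' loss of an essential neighbor: single A full, single B partial or at least
#' better than the double, double null-like), a multiplicative independence
#' scenario (the double's fraction matches the product of the singles within
#' tolerance), or inconclusive.
#'
#' @param single_a,single_b,double `genotype_summary` objects (or bare
#'   fractions) for the two single mutants and the double mutant.
#' @param thresholds Classification thresholds, passed to
#'   [classify_rescue()].
#' @param independence_tol Relative tolerance for the multiplicative check;
#'   an absolute floor of 0.02 applies near zero.
#' @return Object of class `compensation_result` with the three fractions
#'   and `verdict`.
#' @export
compensation_test <- function(single_a, single_b, double,
                              thresholds = c(null_like = 0.10, full = 0.80),
                              independence_tol = 0.25) {
  getf <- function(x) {
    if (inherits(x, "genotype_summary")) x$rescue_fraction
    else if (is.numeric(x) && length(x) == 1L) x
    else stop("missing genotype summary", call. = FALSE)
  }
  fa <- getf(single_a); fb <- getf(single_b); fd <- getf(double)
  ca <- classify_rescue(fa, thresholds)
  cb <- classify_rescue(fb, thresholds)
  cd <- classify_rescue(fd, thresholds)
  verdict <- if (ca == "full" && cd == "null-like" &&
                 (cb == "partial" || fb > fd)) {
    "compensatory"
  } else if (abs(fd - fa * fb) <= max(0.02, independence_tol * fa * fb)) {
    "independent"
  } else {
    "inconclusive"
  }
  structure(list(single_a = fa, single_b = fb, double = fd,
                 class_a = ca, class_b = cb, class_double = cd,
                 verdict = verdict),
            class = "compensation_result")
}

#' @export
print.compensation_result <- function(x, ...) {
  cat(sprintf(
    "<compensation_result> A %.2f (%s), B %.2f (%s), double %.3f (%s) -> %s\n",
    x$single_a, x$class_a, x$single_b, x$class_b, x$double, x$class_double,
    x$verdict))
  invisible(x)
}

#' Exclude lines with fertile non-transgenic control siblings
#'
#' Homozygous mutants are completely sterile in this assay, so any progeny
#' from a line's non-transgenic control siblings indicates recombination;
#' such lines are excluded.  Lines without control broods are retained with a
#' warning entry in the log.
#'
#' @param lines List of [rescue_line()] objects, each optionally carrying
#'   `control_counts`.
#' @return List with `retained`, `excluded` and a `log` data frame.
#' @export
recombinant_filter <- function(lines) {
  entries <- lapply(lines, function(l) {
    ctl <- l$control_counts
    if (is.null(ctl)) {
      data.frame(transgene_id = l$transgene_id, control_total = NA_real_,
                 action = "retained (no controls)")
    } else if (sum(ctl) > 0) {
      data.frame(transgene_id = l$transgene_id, control_total = sum(ctl),
                 action = "excluded (recombinant)")
    } else {
      data.frame(transgene_id = l$transgene_id, control_total = 0,
                 action = "retained")
    }
  })
  log <- do.call(rbind, entries)
  keep <- !grepl("^excluded", log$action)
  if (any(is.na(log$control_total)))
    warning("lines without control broods retained: ",
            paste(log$transgene_id[is.na(log$control_total)], collapse = ", "),
            call. = FALSE)
  list(retained = lines[keep], excluded = lines[!keep], log = log)
}

#' Percentile bootstrap interval for a rescue fraction
#'
#' Resamples line means with replacement within the mutant and reference
#' groups and recomputes the fraction of grand means; descriptive, not a
#' hypothesis test.
#'
#' @param lines,reference Lists of [rescue_line()] objects.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed RNG seed (required, for reproducibility).
#' @param level Interval level (default 0.95).
#' @param weighting Passed to the grand-mean computation.
#' @return Numeric `c(lower, upper)` with attributes `point` and `B`.
#' @export
bootstrap_ci <- function(lines, reference, B = 1000L, seed, level = 0.95,
                         weighting = c("unweighted", "n-weighted")) {
  weighting <- match.arg(weighting)
  stopifnot(B >= 100L)
  if (length(lines) < 2L || length(reference) < 2L)
    warning("single-line group: bootstrap interval is degenerate",
            call. = FALSE)
  m <- line_means(lines); r <- line_means(reference)
  wm <- line_ns(lines); wr <- line_ns(reference)
  agg <- function(x, w) if (weighting == "unweighted") mean(x)
                        else stats::weighted.mean(x, w)
  set.seed(seed)
  frac <- vapply(seq_len(B), function(i) {
    im <- sample.int(length(m), replace = TRUE)
    ir <- sample.int(length(r), replace = TRUE)
    agg(m[im], wm[im]) / agg(r[ir], wr[ir])
  }, 0)
  ci <- stats::quantile(frac, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(ci, point = agg(m, wm) / agg(r, wr), B = B, level = level)
}

#' Read rescue lines from CSV
#'
#' Accepts either long format (`transgene_id, genotype, worm_id,
#' progeny_total`, one row per worm, optional `control_progeny`) or summary
#' format mirroring printed rescue tables (`transgene_id, genotype, mean,
#' sem, n`, optional `table` and `control_brood_total` columns).  A `mean`
#' cell of `"<1"` is ingested as 0.5 and flagged `censored_lt1`.
#'
#' @param path CSV file.
#' @return List of [rescue_line()] objects.
#' @export
read_brood_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) stop("empty brood table", call. = FALSE)
  if (all(c("worm_id", "progeny_total") %in% names(df))) {
    out <- lapply(split(df, df$transgene_id), function(d) {
      ctl <- if ("control_progeny" %in% names(d)) {
        v <- as.numeric(d$control_progeny)
        if (all(is.na(v))) NULL else v[!is.na(v)]
      }
      rescue_line(d$transgene_id[1L], d$genotype[1L],
                  counts = as.numeric(d$progeny_total),
                  control_counts = ctl)
    })
    return(unname(out[unique(df$transgene_id)]))
  }
  if (!all(c("transgene_id", "genotype", "mean", "n") %in% names(df)))
    stop("unrecognized brood CSV layout", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    raw <- trimws(df$mean[i])
    censored <- raw == "<1"
    m <- if (censored) 0.5 else as.numeric(raw)
    s <- if ("sem" %in% names(df) && nzchar(trimws(df$sem[i])))
      as.numeric(df$sem[i]) else 0
    ctl <- if ("control_brood_total" %in% names(df) &&
               nzchar(trimws(df$control_brood_total[i])))
      as.numeric(df$control_brood_total[i])
    rescue_line(df$transgene_id[i], df$genotype[i], mean = m, sem = s,
                n = as.integer(df$n[i]), control_counts = ctl,
                censored_lt1 = censored)
  })
}

#' Split rescue lines by genotype
#'
#' @param lines List of [rescue_line()] objects.
#' @return Named list of line lists, in order of first appearance.
#' @export
split_by_genotype <- function(lines) {
  g <- vapply(lines, `[[`, "", "genotype")
  out <- split(lines, factor(g, levels = unique(g)))
  out
}
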