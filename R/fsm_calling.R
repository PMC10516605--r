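#' Fit a Weibull background-error model for one indel
#'
#' PCR slippage gives every sample a low, right-skewed background VAF at
#' each indel even without a true mutation. That background is modelled per
#' `(locus, offset)` by fitting the VAFs of the wild-type control samples to
#' a two-parameter Weibull distribution by maximum likelihood. Zero VAFs are
#' replaced by a small floor (the Weibull has support on x > 0); by default
#' the floor is `1 / (2 * median control depth)`, half a read.
#'
#' The shape MLE solves the profile likelihood equation
#' `1/k + mean(log x) - sum(x^k log x) / sum(x^k) = 0` by Newton iteration
#' (tolerance `tol`, with a bisection fallback); the scale is then
#' `mean(x^k)^(1/k)`. Degenerate inputs (all controls equal, or shape at the
#' `k_max` cap) are flagged and the model marked unusable; callers fall back
#' to an exact binomial test (see [call_positives()]).
#'
#' @param control_vafs Numeric vector of control VAFs in `[0, 1]`.
#' @param floor_eps Pseudo-VAF replacing zeros. `NULL` derives it from
#'   `control_depths`; `0` disables the floor, in which case zero VAFs are
#'   excluded from the fit.
#' @param control_depths Optional read depths of the control observations,
#'   used to derive the default floor.
#' @param n_min Minimum controls required for a usable fit.
#' @param k_max Cap on the fitted shape.
#' @param tol Convergence tolerance on the shape equation.
#' @return A `weibull_background` object with elements `shape`, `scale`,
#'   `n_controls`, `floor_eps`, `converged`, `degenerate`, `fit_ok`,
#'   `control_mean`.
#' @export
#' @examples
#' set.seed(1)
#' fit_weibull_background(rweibull(200, 1.3, 0.01), floor_eps = 2.5e-4)
fit_weibull_background <- function(control_vafs, floor_eps = NULL,
                                   control_depths = NULL, n_min = 5L,
                                   k_max = 50, tol = 1e-8) {
  x <- control_vafs
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stopf("control VAFs must be in [0, 1]")
  if (is.null(floor_eps)) {
    floor_eps <- if (!is.null(control_depths) && length(control_depths))
      1 / (2 * median(control_depths)) else 0
  }
  if (floor_eps > 0) {
    x[x == 0] <- floor_eps
  } else {
    x <- x[x > 0]
  }
  mk <- function(shape, scale, converged, degenerate) {
    structure(list(locus_id = NA_character_, offset = NA_integer_,
                   shape = shape, scale = scale,
                   n_controls = length(x), floor_eps = floor_eps,
                   converged = converged, degenerate = degenerate,
                   fit_ok = converged && !degenerate && length(x) >= n_min,
                   control_mean = if (length(x)) mean(x) else NA_real_),
              class = "weibull_background")
  }
  if (length(x) < n_min) return(mk(NA_real_, NA_real_, FALSE, FALSE))
  if (sd(x) == 0) return(mk(k_max, x[1], TRUE, TRUE))
  lx <- log(x)
  mlx <- mean(lx)
  g <- function(k) {
    xk <- x^k
    1 / k + mlx - sum(xk * lx) / sum(xk)
  }
  k <- min(max(pi / (sqrt(6) * sd(lx)), 1e-3), k_max)
  converged <- FALSE
  for (i in seq_len(200)) {
    xk <- x^k
    s1 <- sum(xk); s2 <- sum(xk * lx); s3 <- sum(xk * lx^2)
    gk <- 1 / k + mlx - s2 / s1
    gp <- -1 / k^2 - (s3 * s1 - s2^2) / s1^2
    knew <- k - gk / gp
    if (!is.finite(knew) || knew <= 0) knew <- k / 2
    if (knew > k_max) knew <- k_max
    if (abs(knew - k) < tol) {
      k <- knew
      converged <- TRUE
      break
    }
    k <- knew
  }
  if (!converged || (k >= k_max - tol && g(k_max) > 0)) {
    # Newton stalled or capped: the shape equation is monotone decreasing,
    # so bracket and bisect; g(k_max) > 0 means the root lies beyond the cap.
    if (g(k_max) > 0) {
      k <- k_max
      converged <- TRUE
    } else {
      root <- tryCatch(uniroot(g, c(1e-3, k_max), tol = tol),
                       error = function(e) NULL)
      if (is.null(root)) return(mk(NA_real_, NA_real_, FALSE, FALSE))
      k <- root$root
      converged <- TRUE
    }
  }
  lambda <- mean(x^k)^(1 / k)
  mk(k, lambda, converged, degenerate = k >= k_max - tol)
}

#' @export
print.weibull_background <- function(x, ...) {
  cat(sprintf(
    "<weibull_background %s offset %s: shape %.3f, scale %.3g, n = %d%s>\n",
    x$locus_id, x$offset, x$shape, x$scale, x$n_controls,
    if (!x$fit_ok) " [unfit]" else ""))
  invisible(x)
}

#' Upper-tail background p-value for a VAF
#'
#' The one-sided probability that background error alone produces a VAF at
#' least this large: `p = exp(-(max(vaf, eps) / scale)^shape)`, the Weibull
#' survival function evaluated at the (floored) VAF. One-sided because
#' positivity means "significantly above background".
#'
#' @param model A usable [fit_weibull_background()] model.
#' @param vaf Numeric vector of VAFs in `[0, 1]`.
#' @return p-values in `(0, 1]`.
#' @export
weibull_pvalue <- function(model, vaf) {
  if (!inherits(model, "weibull_background")) stopf("not a weibull_background")
  if (!model$fit_ok)
    stopf("model is not usable (unfit or degenerate); use the binomial fallback")
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) stopf("vaf must be in [0, 1]")
  exp(-(pmax(vaf, model$floor_eps) / model$scale)^model$shape)
}

# Exact binomial fallback when no Weibull background can be fitted: is the
# mutant read count consistent with a background rate of
# p0 = max(floor, mean control VAF)?
binom_background_pvalue <- function(mutant_reads, denom, p0) {
  pbinom(mutant_reads - 1L, denom, p0, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (with the usual monotonicity enforcement) across a
#' family of p-values; a thin wrapper over [stats::p.adjust()].
#'
#' @param p_values Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

#' Fit background models for every indel in a count table
#'
#' @param counts Indel count table from [tabulate_indels()].
#' @param samples Sample sheet: data frame with `sample_id`, `group`
#'   (controls have group `"wt_control"`).
#' @param floor_eps,n_min Passed to [fit_weibull_background()]; the default
#'   floor is derived per indel from the median control depth.
#' @return Named list of `weibull_background` models keyed
#'   `"locus_id|offset"`.
#' @export
fit_background_models <- function(counts, samples, floor_eps = NULL,
                                  n_min = 5L) {
  controls <- samples$sample_id[samples$group == "wt_control"]
  if (!length(controls)) stopf("sample sheet contains no wt_control samples")
  ctl <- counts[counts$sample_id %in% controls & !is.na(counts$vaf), ,
                drop = FALSE]
  keys <- unique(paste(counts$locus_id, counts$offset, sep = "|"))
  models <- list()
  for (key in keys) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sub <- ctl[ctl$locus_id == parts[1] & ctl$offset == as.integer(parts[2]), ,
               drop = FALSE]
    m <- fit_weibull_background(sub$vaf, floor_eps = floor_eps,
                                control_depths = sub$total_usable,
                                n_min = n_min)
    m$locus_id <- parts[1]
    m$offset <- as.integer(parts[2])
    models[[key]] <- m
  }
  models
}

#' Call FSM-positive samples against the fitted background
#'
#' Every non-control sample row in the count table is tested one-sided
#' against its indel's background model; p-values are pooled across the full
#' sample-by-indel family in a single Benjamini-Hochberg batch, and a row is
#' positive when its adjusted q-value falls below `alpha` (strictly). Control
#' samples are never tested against their own background. Indels whose
#' background could not be fitted (too few controls, or a degenerate fit)
#' fall back to an exact binomial test of the mutant read count against
#' `max(floor, mean control VAF)`.
#'
#' @param counts Indel count table from [tabulate_indels()].
#' @param samples Sample sheet (`sample_id`, `group`).
#' @param models Background models from [fit_background_models()]; fitted on
#'   the fly when `NULL`.
#' @param alpha Significance threshold in `(0, 1]`.
#' @param threshold `"adjusted"` (default) thresholds the BH q-value;
#'   `"raw"` thresholds the unadjusted p-value.
#' @param floor_eps,n_min Passed to [fit_background_models()] when models
#'   are fitted here.
#' @return A call matrix: `sample_id`, `locus_id`, `offset`, `vaf`,
#'   `p_value`, `q_value`, `positive`, `method` (`"weibull"` or
#'   `"binomial"`).
#' @export
call_positives <- function(counts, samples, models = NULL, alpha = 0.05,
                           threshold = c("adjusted", "raw"),
                           floor_eps = NULL, n_min = 5L) {
  threshold <- match.arg(threshold)
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (is.null(models))
    models <- fit_background_models(counts, samples, floor_eps, n_min)
  grp <- setNames(samples$group, samples$sample_id)
  test <- counts[grp[counts$sample_id] != "wt_control", , drop = FALSE]
  skip_na <- is.na(test$vaf)
  if (any(skip_na)) {
    warning(sprintf("%d row(s) without coverage skipped", sum(skip_na)),
            call. = FALSE)
    test <- test[!skip_na, , drop = FALSE]
  }
  keys <- paste(test$locus_id, test$offset, sep = "|")
  p <- rep(NA_real_, nrow(test))
  method <- rep(NA_character_, nrow(test))
  missing_keys <- character(0)
  fallback_keys <- character(0)
  for (key in unique(keys)) {
    i <- which(keys == key)
    m <- models[[key]]
    if (is.null(m)) {
      missing_keys <- c(missing_keys, key)
      next
    }
    if (m$fit_ok) {
      p[i] <- weibull_pvalue(m, test$vaf[i])
      method[i] <- "weibull"
    } else {
      p0 <- max(m$floor_eps, m$control_mean, na.rm = TRUE)
      if (!is.finite(p0) || p0 <= 0) {
        missing_keys <- c(missing_keys, key)
        next
      }
      p[i] <- binom_background_pvalue(test$mutant_reads[i],
                                      test$mutant_reads[i] + test$wt_reads[i],
                                      p0)
      method[i] <- "binomial"
      fallback_keys <- c(fallback_keys, key)
    }
  }
  if (length(missing_keys))
    warning(sprintf("no background model for %s; rows skipped",
                    paste(unique(missing_keys), collapse = ", ")),
            call. = FALSE)
  if (length(fallback_keys))
    warning(sprintf("binomial fallback used for %s",
                    paste(unique(fallback_keys), collapse = ", ")),
            call. = FALSE)
  keep <- !is.na(p)
  test <- test[keep, , drop = FALSE]
  p <- p[keep]
  method <- method[keep]
  q <- fdr_adjust(p)
  positive <- if (threshold == "adjusted") q < alpha else p < alpha
  data.frame(sample_id = test$sample_id, locus_id = test$locus_id,
             offset = test$offset, vaf = test$vaf, p_value = p, q_value = q,
             positive = positive, method = method, row.names = NULL)
}

#' Cohort mutation frequencies
#'
#' Per `(locus, offset, group)` fraction of tested samples called positive
#' — the cohort-frequency summary reported for frameshift targets.
#'
#' @param calls Call matrix from [call_positives()].
#' @param samples Sample sheet (`sample_id`, `group`).
#' @return Data frame `locus_id`, `offset`, `group`, `n_samples`,
#'   `n_positive`, `frequency`.
#' @export
mutation_frequency <- function(calls, samples) {
  grp <- setNames(samples$group, samples$sample_id)
  calls$group <- grp[calls$sample_id]
  if (any(is.na(calls$group)))
    stopf("calls contain samples missing from the sample sheet")
  agg <- aggregate(cbind(n_samples = positive, n_positive = positive) ~
                     locus_id + offset + group, data = calls,
                   FUN = length)
  pos <- aggregate(positive ~ locus_id + offset + group, data = calls,
                   FUN = sum)
  out <- merge(agg[c("locus_id", "offset", "group", "n_samples")], pos,
               by = c("locus_id", "offset", "group"))
  names(out)[names(out) == "positive"] <- "n_positive"
  out$frequency <- out$n_positive / out$n_samples
  out[order(out$locus_id, out$offset, out$group), , drop = FALSE]
}
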