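#' Fit the site-level expression-change HMM for one sample strain
#'
#' The main entry point of the package. Takes per-site coverage for one
#' chromosome across the reference replicates and sample strains, quantile
#' normalizes across samples (optional), summarizes the reference
#' replicates per site, builds the three-state emission model from the log
#' fold change of the chosen sample against the reference mean, optionally
#' re-estimates the transition matrix by Baum-Welch, and decodes per-site
#' posterior state probabilities by forward-backward.
#'
#' @param cm A [coverage_matrix] holding the reference replicates and sample
#'   strains for one chromosome and one tissue.
#' @param sample Name of the sample column to decode.
#' @param ref_samples Character vector of reference replicate column names.
#' @param normalize Quantile normalize across all columns first
#'   (default TRUE; set FALSE if `cm` is already normalized).
#' @param hmm An [hmm_params] (initial/transition probabilities).
#' @param emission An [emission_params].
#' @param baum_welch If TRUE, re-estimate `pi0` and the transition matrix on
#'   this chain before decoding.
#' @param ... Passed to [baum_welch_transitions()] (`max_iter`, `tol`).
#' @return An object of class `expr_hmm`: the fitted site-level model, with
#'   components `chrom`, `positions`, `sample`, `mu`, `sigma2`,
#'   `sample_cov`, `lfc`, `posterior`, `state`, `loglik`, `params`
#'   (`hmm_params` used for decoding) and `emission` (parameters).
#' @seealso [call_blocks()], [classify_gene_regions()], [detect_de_novo()]
#'   for downstream calls; [summary.expr_hmm()], [plot.expr_hmm()].
#' @export
#' @examples
#' sim <- simulate_coverage(sim_config(seed = 1, chrom_length = 20000,
#'                                     n_genes = 4, n_strains = 2))
#' fit <- expr_hmm(sim$coverage, sample = "S1", ref_samples = sim$ref_samples)
#' summary(fit)
expr_hmm <- function(cm, sample, ref_samples, normalize = TRUE,
                     hmm = hmm_params(), emission = emission_params(),
                     baum_welch = FALSE, ...) {
  stopifnot(inherits(cm, "coverage_matrix"))
  miss <- setdiff(c(sample, ref_samples), cm$samples)
  if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
  if (length(ref_samples) < 2L) stop("need >= 2 reference replicates")
  if (normalize) cm <- quantile_normalize(cm)
  ref <- summarize_reference(cm, samples = ref_samples)
  sample_cov <- cm$depth[, sample]
  em <- emission_probs(sample_cov, ref, emission)
  params <- hmm
  bw <- NULL
  if (isTRUE(baum_welch)) {
    params <- baum_welch_transitions(em$e, start = hmm, ...)
    bw <- params
  }
  track <- forward_backward(em$e, params, positions = cm$positions)
  structure(list(chrom = cm$chrom, positions = cm$positions, sample = sample,
                 ref_samples = ref_samples, mu = ref$mu, sigma2 = ref$sigma2,
                 sample_cov = sample_cov, lfc = em$L,
                 posterior = track$posterior, state = track$state,
                 loglik = track$loglik, params = params, emission = emission,
                 baum_welch = bw, normalized = normalize),
            class = "expr_hmm")
}

#' @export
print.expr_hmm <- function(x, ...) {
  cat(sprintf("expr_hmm fit: sample %s vs %d reference replicates\n",
              x$sample, length(x$ref_samples)))
  cat(sprintf("  %s: %d sites, logLik %.2f\n", x$chrom, length(x$positions),
              x$loglik))
  tab <- table(factor(x$state, levels = 0:2,
                      labels = c("down", "stable", "up")))
  cat(sprintf("  states: down %d, stable %d, up %d (background up rate %.4f)\n",
              tab[1L], tab[2L], tab[3L], mean(x$state == 2L)))
  invisible(x)
}

#' Summarize a fitted expression HMM
#'
#' State counts, the genome-wide (chromosome-wide) up-site background rate,
#' and the expression blocks of at least `min_len` bp.
#'
#' @param object An `expr_hmm` fit.
#' @param min_len Minimum block length in bp (default 50).
#' @param ... Unused.
#' @return An object of class `summary.expr_hmm`.
#' @export
summary.expr_hmm <- function(object, min_len = 50, ...) {
  blocks <- call_blocks(object, min_len = min_len)
  out <- list(sample = object$sample, chrom = object$chrom,
              n_sites = length(object$positions),
              state_counts = table(factor(object$state, levels = 0:2,
                                          labels = c("down", "stable", "up"))),
              background_up = mean(object$state == 2L),
              background_down = mean(object$state == 0L),
              min_len = min_len, blocks = blocks, loglik = object$loglik,
              params = object$params)
  class(out) <- "summary.expr_hmm"
  out
}

#' @export
print.summary.expr_hmm <- function(x, ...) {
  cat(sprintf("expr_hmm fit: sample %s on %s (%d sites)\n", x$sample, x$chrom,
              x$n_sites))
  print(x$state_counts)
  cat(sprintf("background rates: up %.4f, down %.4f\n", x$background_up,
              x$background_down))
  cat(sprintf("%d expression blocks >= %d bp (%d up, %d down)\n",
              nrow(x$blocks), x$min_len, sum(x$blocks$state == 2L),
              sum(x$blocks$state == 0L)))
  invisible(x)
}

#' @export
coef.expr_hmm <- function(object, ...) {
  list(pi0 = object$params$pi0, trans = object$params$trans,
       alpha = object$emission$alpha)
}

#' Residuals of the expression HMM fit
#'
#' `type = "lfc"` (default) returns the per-site natural-log fold change of
#' sample coverage against the reference mean (`NA` at low-coverage sites,
#' where the fold-change model is bypassed); `type = "z"` standardizes it by
#' the delta-method sd, giving the test statistic the emission model scores.
#'
#' @param object An `expr_hmm` fit.
#' @param type `"lfc"` or `"z"`.
#' @param ... Unused.
#' @export
residuals.expr_hmm <- function(object, type = c("lfc", "z"), ...) {
  type <- match.arg(type)
  if (type == "lfc") return(object$lfc)
  s <- delta_lfc_sd(object$mu, object$sigma2,
                    object$emission$low_mu_threshold,
                    object$emission$sigma2_floor)
  object$lfc / s
}

#' @export
fitted.expr_hmm <- function(object, ...) object$posterior

#' Simulate state paths from a fitted expression HMM
#'
#' Draws Markov state sequences of the chain's length from the fitted
#' initial and transition probabilities (emissions are a per-site model, so
#' only state paths are simulated).
#'
#' @param object An `expr_hmm` fit.
#' @param nsim Number of paths.
#' @param seed Optional seed, restored afterwards via the usual
#'   `simulate()` convention.
#' @param ... Unused.
#' @return A data.frame with one column per simulated path (state codes
#'   0/1/2), `seed` attribute set.
#' @export
simulate.expr_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$positions)
  out <- replicate(nsim, simulate_state_path(n, object$params))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

simulate_state_path <- function(n, params) {
  st <- integer(n)
  st[1L] <- sample.int(3L, 1L, prob = params$pi0) - 1L
  if (n > 1L) for (t in 2:n)
    st[t] <- sample.int(3L, 1L, prob = params$trans[st[t - 1L] + 1L, ]) - 1L
  st
}

#' Plot a fitted expression HMM
#'
#' Coverage track for the sample (red) over the reference mean (grey), with
#' the decoded state shown underneath (up/down sites only, in blue), the
#' layout used for locus figures in this field.
#'
#' @param x An `expr_hmm` fit.
#' @param region Optional `c(start, end)` to restrict the plotted window.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.expr_hmm <- function(x, region = NULL, ...) {
  i <- seq_along(x$positions)
  if (!is.null(region))
    i <- which(x$positions >= region[1L] & x$positions <= region[2L])
  pos <- x$positions[i]
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(pos, x$mu[i], type = "l", col = "grey50",
                 xlab = sprintf("%s position (bp)", x$chrom),
                 ylab = "normalized coverage",
                 ylim = c(0, max(x$mu[i], x$sample_cov[i], 1)), ...)
  graphics::lines(pos, x$sample_cov[i], col = "red3")
  chg <- i[x$state[i] != 1L]
  if (length(chg)) {
    y <- ifelse(x$state[chg] == 2L, 1, -1)
    graphics::points(x$positions[chg],
                     rep(graphics::par("usr")[4L] * 0.98, length(chg)),
                     pch = "|", col = ifelse(y > 0, "blue", "steelblue"),
                     cex = 0.4)
  }
  graphics::legend("topleft", legend = c("reference mean", x$sample, "state != stable"),
                   col = c("grey50", "red3", "blue"), lty = c(1, 1, NA),
                   pch = c(NA, NA, "|"), bty = "n", cex = 0.8)
  invisible(x)
}
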