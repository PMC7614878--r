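#' Spike-in calibrated highly variable gene selection
#'
#' Brennecke-style selection: spike-ins are pure technical noise, so the
#' relation of their squared coefficient of variation to their mean,
#' \eqn{CV^2_{tech}(\mu) = a_1/\mu + \alpha_0}, fitted by gamma GLM with
#' identity link, calibrates the technical variability expected at any
#' expression level. Each biological gene's observed CV\eqn{^2} (on
#' counts normalized by size factors computed separately for biological
#' genes and spike-ins) is tested against the fitted technical
#' CV\eqn{^2} plus a minimum biological dispersion via the chi-squared
#' ratio test \eqn{(n-1)\,CV^2_{obs} / (CV^2_{fit} + d_{min}) \sim
#' \chi^2_{n-1}}, and genes are selected at a Benjamini-Hochberg FDR.
#'
#' @param x `SingleCellExperiment` with a `"counts"` assay and >= 10
#'   spike-in genes of nonzero mean.
#' @param fdr Benjamini-Hochberg threshold.
#' @param min_biol_disp minimum squared biological coefficient of
#'   variation a gene must exceed technical noise by.
#' @return data.frame over biological genes: `gene`, `mean`, `cv2`,
#'   `tech_cv2`, `p`, `padj`, `selected`.
#' @export
select_hvg_spikein <- function(x, fdr = 0.1, min_biol_disp = 0.25) {
  counts <- as.matrix(.get_layer(x, "counts"))
  spike <- spikein_mask(x)
  sp <- counts[spike, , drop = FALSE]
  bio <- counts[!spike, , drop = FALSE]
  if (sum(rowMeans(sp) > 0) < 10)
    stop("fewer than 10 spike-ins with nonzero mean; use ",
         "fallback_hvg_dispersion() for spike-in-free data")
  norm_part <- function(m) {
    totals <- colSums(m)
    if (any(totals <= 0)) totals[totals <= 0] <- mean(totals[totals > 0])
    t(t(m) / (totals / mean(totals)))
  }
  spn <- norm_part(sp)
  bion <- norm_part(bio)
  moments <- function(m) {
    mu <- rowMeans(m)
    v <- apply(m, 1, stats::var)
    data.frame(mean = mu, cv2 = ifelse(mu > 0, v / mu^2, 0))
  }
  ms <- moments(spn)
  ms <- ms[ms$mean > 0, ]
  fit <- .fit_tech_cv2(ms$mean, ms$cv2)
  mb <- moments(bion)
  tech <- pmax(fit["a1"] / pmax(mb$mean, 1e-12) + fit["a0"], 1e-8)
  df <- ncol(bio) - 1L
  chi2 <- mb$cv2 * df / (tech + min_biol_disp)
  p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  p[mb$mean <= 0] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(bio), mean = mb$mean, cv2 = mb$cv2,
                    tech_cv2 = tech, p = p, padj = padj,
                    selected = padj < fdr, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

# Gamma-GLM (identity link) fit of cv2 ~ a1/mu + a0 on spike-ins,
# falling back to ordinary least squares if the GLM does not converge.
.fit_tech_cv2 <- function(mu, cv2) {
  inv <- 1 / mu
  start <- stats::coef(stats::lm(cv2 ~ inv))
  co <- tryCatch({
    g <- stats::glm(cv2 ~ inv, family = stats::Gamma(link = "identity"),
                    start = pmax(start, c(1e-4, 1e-4)))
    stats::coef(g)
  }, error = function(e) start, warning = function(w) start)
  c(a0 = max(unname(co[1]), 0), a1 = max(unname(co[2]), 1e-12))
}

#' Dispersion-based highly variable genes (no spike-ins)
#'
#' Mean/dispersion selection on the log layer for datasets without
#' spike-ins: per gene the mean and dispersion (variance/mean) of
#' `expm1(log expression)` are computed, genes are cut into 20
#' equal-frequency mean bins, dispersions are z-scored within each bin,
#' and a gene is selected when its mean lies inside
#' `[min_mean, max_mean]` and its normalized dispersion reaches
#' `min_disp`.
#'
#' @param x `SingleCellExperiment` with a `"logcounts"` layer.
#' @param min_mean,max_mean mean-expression window (on the expm1 scale).
#' @param min_disp minimum bin-normalized dispersion.
#' @param n_bins number of mean bins.
#' @return data.frame over biological genes: `gene`, `mean`,
#'   `dispersion`, `dispersion_norm`, `selected`.
#' @export
fallback_hvg_dispersion <- function(x, min_mean = 0.02, max_mean = 3,
                                    min_disp = 0.3, n_bins = 20L) {
  m <- as.matrix(.get_layer(x, "logcounts"))
  m <- expm1(m[!spikein_mask(x), , drop = FALSE])
  mu <- rowMeans(m)
  v <- apply(m, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  in_window <- mu >= min_mean & mu <= max_mean
  if (!any(in_window))
    stop("no genes fall inside the [min_mean, max_mean] window")
  # equal-frequency bins on the mean, deterministic under ties
  ord <- order(mu, rownames(m))
  pos <- integer(length(mu)); pos[ord] <- seq_along(mu)
  bin <- ceiling(pos * n_bins / length(mu))
  disp_norm <- disp
  for (b in unique(bin)) {
    i <- bin == b
    s <- stats::sd(disp[i])
    disp_norm[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  data.frame(gene = rownames(m), mean = mu, dispersion = disp,
             dispersion_norm = disp_norm,
             selected = in_window & disp_norm >= min_disp,
             stringsAsFactors = FALSE)
}
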