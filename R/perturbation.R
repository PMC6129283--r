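# Artificial batch effects: Gaussian noise added to a fraction of samples,
# fraction and intensity sweeps, and the adjust-and-rescore loop.

# round half away from zero, so e.g. 0.5 * 15 = 7.5 -> 8
.round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# allocate a total of m picks across groups proportionally to group size,
# largest remainder method, so the overall count is exactly m while every
# group is represented as evenly as possible
.allocate_stratified <- function(group_sizes, m) {
  quota <- group_sizes / sum(group_sizes) * m
  base <- floor(quota)
  rem <- m - sum(base)
  if (rem > 0L) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  base
}

#' Add Gaussian noise to a fraction of samples (artificial batch effect)
#'
#' Selects `round(fraction * n)` samples (half away from zero) and adds an
#' independent `N(mu, sigma^2)` draw to every gene value of each selected
#' sample. Unselected samples are returned bit-identical. With stratified
#' selection (the default when `group` labels are available) the noisy
#' samples are spread across groups by largest-remainder allocation, so every
#' group contains both the clean and the noisy batch while the total count is
#' exact. Values are not clipped: on a log scale a negative value is
#' meaningful, and clipping would distort the injected shift.
#'
#' @param expr Genes x samples numeric matrix (on whatever scale downstream
#'   scoring will consume; see Details of [noise_fraction_sweep()]).
#' @param fraction Fraction of samples to contaminate, in `[0, 1]`.
#' @param mu,sigma Mean and standard deviation of the noise; defaults 10 and 1.
#' @param seed Integer seed; selection and noise draws are reproducible.
#' @param group Optional character vector of group labels (named by sample id
#'   or aligned with columns); enables stratified selection.
#' @param stratify Stratify the selection by `group`? Default `TRUE` when
#'   `group` is supplied.
#' @return List with `expr` (noisy matrix), `batch` (named character vector,
#'   `"clean"`/`"noisy"`), and `noise` (the injected genes x noisy-samples
#'   matrix, for oracle adjustment).
#' @export
add_gaussian_noise <- function(expr, fraction, mu = 10, sigma = 1, seed = 1,
                               group = NULL, stratify = !is.null(group)) {
  validate_expression(expr)
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]")
  }
  if (sigma <= 0) stop("sigma must be > 0")
  samples <- colnames(expr)
  n <- length(samples)
  m <- as.integer(.round_half_away(fraction * n))
  set.seed(seed)
  if (m == 0L) {
    return(list(expr = expr,
                batch = stats::setNames(rep("clean", n), samples),
                noise = matrix(0, nrow(expr), 0)))
  }
  if (stratify) {
    if (is.null(group)) stop("stratified selection needs group labels")
    if (!is.null(names(group))) group <- group[samples]
    if (length(group) != n || any(is.na(group))) {
      stop("group labels must cover every sample")
    }
    by_group <- split(samples, group)
    counts <- .allocate_stratified(lengths(by_group), m)
    noisy <- unlist(mapply(function(s, k) sample(s, k),
                           by_group, counts, SIMPLIFY = FALSE),
                    use.names = FALSE)
  } else {
    noisy <- sample(samples, m)
  }
  noise <- matrix(stats::rnorm(nrow(expr) * length(noisy), mean = mu, sd = sigma),
                  nrow = nrow(expr),
                  dimnames = list(rownames(expr), noisy))
  out <- expr
  out[, noisy] <- out[, noisy] + noise
  batch <- stats::setNames(rep("clean", n), samples)
  batch[noisy] <- "noisy"
  list(expr = out, batch = batch, noise = noise)
}

# shared driver for the two sweeps: returns one summary row per axis value
.sweep_scores <- function(expr, graph, mapping, axis_name, axis_values,
                          noise_args_fn, seed, noise_scale, measure, cor,
                          n_pcs, log_transform, include_self) {
  mapping <- validate_mapping(mapping, graph)
  group <- if ("group" %in% names(mapping)) {
    stats::setNames(as.character(mapping$group), mapping$sample_id)
  } else NULL
  base <- if (noise_scale == "post") {
    preprocess_expression(expr, log_transform = log_transform)
  } else {
    expr
  }
  rows <- vector("list", length(axis_values))
  per_sample <- vector("list", length(axis_values))
  for (i in seq_along(axis_values)) {
    na <- noise_args_fn(axis_values[[i]])
    noisy <- add_gaussian_noise(base, fraction = na$fraction, mu = na$mu,
                                sigma = na$sigma, seed = seed + i,
                                group = group)
    u <- score_expression(noisy$expr, graph, mapping, measure = measure,
                          cor = cor, n_pcs = n_pcs,
                          log_transform = if (noise_scale == "post") FALSE
                                          else log_transform,
                          include_self = include_self)
    s <- u$score
    rows[[i]] <- data.frame(
      axis = axis_values[[i]],
      n = length(s),
      n_na = sum(is.na(s)),
      mean = mean(s, na.rm = TRUE),
      median = stats::median(s, na.rm = TRUE),
      q25 = unname(stats::quantile(s, 0.25, na.rm = TRUE, names = FALSE)),
      q75 = unname(stats::quantile(s, 0.75, na.rm = TRUE, names = FALSE))
    )
    per_sample[[i]] <- s
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- axis_name
  names(per_sample) <- as.character(axis_values)
  attr(out, "scores") <- per_sample
  out
}

#' Sweep the contaminated sample fraction
#'
#' Reruns the full pipeline (noise injection, PCA, observed similarity,
#' scoring) at each contamination fraction and summarises the score
#' distribution per fraction. By default (`noise_scale = "post"`) the noise is
#' injected on the same scale the scoring consumes, i.e. after the log
#' transform; `noise_scale = "raw"` injects into the raw matrix before
#' preprocessing instead.
#'
#' @param expr Genes x samples expression matrix (raw scale).
#' @param graph,mapping Ontology and sample mapping.
#' @param fractions Contamination fractions; default `c(0, 0.1, ..., 0.5)`.
#' @param mu,sigma Noise parameters; defaults 10 and 1.
#' @param seed Base seed; fraction i uses `seed + i`.
#' @param noise_scale `"post"` (default) or `"raw"`, see Details.
#' @param measure,cor,n_pcs,log_transform,include_self Scoring configuration.
#' @return Data frame with one row per fraction (`fraction`, `n`, `n_na`,
#'   `mean`, `median`, `q25`, `q75`); attribute `"scores"` holds the
#'   per-fraction score vectors.
#' @export
noise_fraction_sweep <- function(expr, graph, mapping,
                                 fractions = seq(0, 0.5, by = 0.1),
                                 mu = 10, sigma = 1, seed = 1,
                                 noise_scale = c("post", "raw"),
                                 measure = "cosine", cor = "spearman",
                                 n_pcs = 4, log_transform = TRUE,
                                 include_self = TRUE) {
  noise_scale <- match.arg(noise_scale)
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  .sweep_scores(expr, graph, mapping, "fraction", fractions,
                function(f) list(fraction = f, mu = mu, sigma = sigma),
                seed, noise_scale, measure, cor, n_pcs, log_transform,
                include_self)
}

#' Sweep the noise intensity (mean of the Gaussian shift)
#'
#' Holds the contaminated fraction fixed (default 50% of samples) and varies
#' the mean of the injected Gaussian noise.
#'
#' @param expr,graph,mapping As in [noise_fraction_sweep()].
#' @param mus Noise means to test; default `c(0, 10, 20, 30)`.
#' @param sigma Noise standard deviation; default 1.
#' @param fraction Contaminated fraction; default 0.5.
#' @param seed,noise_scale,measure,cor,n_pcs,log_transform,include_self As in
#'   [noise_fraction_sweep()].
#' @return Data frame with one row per `mu`; attribute `"scores"` as above.
#' @export
noise_intensity_sweep <- function(expr, graph, mapping,
                                  mus = c(0, 10, 20, 30),
                                  sigma = 1, fraction = 0.5, seed = 1,
                                  noise_scale = c("post", "raw"),
                                  measure = "cosine", cor = "spearman",
                                  n_pcs = 4, log_transform = TRUE,
                                  include_self = TRUE) {
  noise_scale <- match.arg(noise_scale)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  .sweep_scores(expr, graph, mapping, "mu", mus,
                function(m) list(fraction = fraction, mu = m, sigma = sigma),
                seed, noise_scale, measure, cor, n_pcs, log_transform,
                include_self)
}

#' Score a dataset before noise, after noise, and after batch adjustment
#'
#' Computes three matched per-sample ontology score vectors: on the clean
#' matrix, on the noisy matrix, and on the noisy matrix after applying a
#' batch adjuster. The adjuster may be the name of a registered adjuster (see
#' [register_adjuster()]) or a function `(expr, batch, group) -> expr`
#' returning a matrix with an unchanged sample roster.
#'
#' All three matrices are scored with the same configuration. When the noise
#' was injected post-transform (the default of the sweeps), pass the
#' log-scale matrices and `log_transform = FALSE`.
#'
#' @param expr_clean,expr_noisy Genes x samples matrices, same roster.
#' @param batch Named character vector of batch labels (e.g. from
#'   [add_gaussian_noise()]).
#' @param graph,mapping Ontology and sample mapping.
#' @param adjuster Registered adjuster name or function; default
#'   `"location_scale"`.
#' @param measure,cor,n_pcs,log_transform,include_self Scoring configuration.
#' @return Data frame of class `adjustment_scores`: `sample_id`, optional
#'   `group`, and score columns `original`, `noisy`, `adjusted`.
#' @export
adjust_and_rescore <- function(expr_clean, expr_noisy, batch, graph, mapping,
                               adjuster = "location_scale",
                               measure = "cosine", cor = "spearman",
                               n_pcs = 4, log_transform = FALSE,
                               include_self = TRUE) {
  mapping <- validate_mapping(mapping, graph)
  if (!identical(colnames(expr_clean), colnames(expr_noisy))) {
    stop("clean and noisy matrices must cover the same samples in order")
  }
  fn <- if (is.function(adjuster)) adjuster else get_adjuster(adjuster)
  group <- if ("group" %in% names(mapping)) {
    stats::setNames(as.character(mapping$group), mapping$sample_id)
  } else NULL
  adjusted <- fn(expr_noisy, batch[colnames(expr_noisy)], group)
  if (!identical(colnames(adjusted), colnames(expr_noisy)) ||
      !identical(rownames(adjusted), rownames(expr_noisy))) {
    stop("adjuster changed the gene/sample roster; contract violation")
  }
  score1 <- function(m) {
    score_expression(m, graph, mapping, measure = measure, cor = cor,
                     n_pcs = n_pcs, log_transform = log_transform,
                     include_self = include_self)
  }
  u_orig <- score1(expr_clean)
  u_noisy <- score1(expr_noisy)
  u_adj <- score1(adjusted)
  out <- data.frame(sample_id = u_orig$sample_id,
                    original = u_orig$score,
                    noisy = u_noisy$score,
                    adjusted = u_adj$score,
                    stringsAsFactors = FALSE)
  if (!is.null(group)) out$group <- group[out$sample_id]
  structure(out, class = c("adjustment_scores", "data.frame"),
            adjuster = if (is.function(adjuster)) "<function>" else adjuster)
}
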