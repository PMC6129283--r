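# Control-gene probabilities and a baseline location-scale batch adjuster,
# plus a registry so external adjusters can be plugged in by name.

#' Control-gene probabilities from standard-deviation ranks
#'
#' Assigns each gene a probability of being a control gene from the rank of
#' its standard deviation across all samples:
#' `pc = 1 - rank(sd) / max(rank(sd))`, with ascending ranks (smallest sd is
#' rank 1) and average ranks for ties. Genes with stable expression across
#' samples therefore receive probabilities near 1 and the most variable gene
#' receives exactly 0 — control genes should vary as little as possible.
#'
#' @param expr Genes x samples numeric matrix with >= 2 samples.
#' @return Data frame with columns `gene_id`, `sd`, `rank`, `pc`.
#' @export
control_gene_probabilities <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) < 2L) stop("need at least 2 samples to estimate per-gene sd")
  sds <- apply(expr, 1L, stats::sd)
  r <- rank(sds)  # ascending, average ranks for ties
  pc <- 1 - r / max(r)
  data.frame(gene_id = rownames(expr), sd = sds, rank = r, pc = pc,
             row.names = NULL, stringsAsFactors = FALSE)
}

# population (divide-by-n) moments per gene over a column subset; the
# population form makes the adjuster exactly idempotent
.row_moments <- function(m) {
  mu <- rowMeans(m)
  sd <- sqrt(rowMeans((m - mu)^2))
  list(mean = mu, sd = sd)
}

#' Baseline two-moment (location-scale) batch adjuster
#'
#' Transforms each batch so that every gene has the same mean and standard
#' deviation across batches: per gene, each batch's values are standardized
#' by that batch's moments, then rescaled to the overall mean and to the
#' within-batch variance pooled across batches (rescaling to the total
#' variance would inflate every batch by the between-batch separation being
#' removed). This is the common core of location-scale batch adjustment,
#' without empirical-Bayes shrinkage of the per-gene estimates.
#'
#' With `group` labels supplied (and `preserve_groups = TRUE`), batch moments
#' are estimated on group-centered residuals — the per-gene group means are
#' removed first, the residuals are batch-standardized, and the group means
#' are added back — so biological group differences survive the adjustment.
#'
#' Population (divide-by-n) moments are used throughout, which makes the
#' adjustment exactly idempotent. A batch with zero variance for a gene is
#' recentred to the pooled mean without rescaling.
#'
#' @param expr Genes x samples numeric matrix.
#' @param batch Character vector of batch labels, named by sample id or
#'   aligned with columns; every batch needs >= 2 samples.
#' @param group Optional group labels (same conventions as `batch`).
#' @param preserve_groups Estimate batch effects on group-centered residuals?
#'   Default `TRUE` when `group` is supplied.
#' @return Adjusted matrix, same dimnames as the input.
#' @export
adjust_location_scale <- function(expr, batch, group = NULL,
                                  preserve_groups = !is.null(group)) {
  validate_expression(expr)
  samples <- colnames(expr)
  if (!is.null(names(batch))) batch <- batch[samples]
  if (length(batch) != ncol(expr) || any(is.na(batch))) {
    stop("batch labels must cover every sample")
  }
  batch <- as.character(batch)
  tab <- table(batch)
  if (any(tab < 2L)) {
    stop("batch with fewer than 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  if (preserve_groups) {
    if (is.null(group)) stop("preserve_groups = TRUE needs group labels")
    if (!is.null(names(group))) group <- group[samples]
    if (length(group) != ncol(expr) || any(is.na(group))) {
      stop("group labels must cover every sample")
    }
    group <- as.character(group)
    # per-gene group means, removed before and restored after adjustment
    gm <- vapply(unique(group),
                 function(g) rowMeans(expr[, group == g, drop = FALSE]),
                 numeric(nrow(expr)))
    fitted <- gm[, group, drop = FALSE]
    resid <- expr - fitted
    adj <- .adjust_moments(resid, batch)
    out <- fitted + adj
  } else {
    out <- .adjust_moments(expr, batch)
  }
  dimnames(out) <- dimnames(expr)
  out
}

.adjust_moments <- function(m, batch) {
  pooled_mean <- rowMeans(m)
  ub <- unique(batch)
  moments <- lapply(ub, function(b) .row_moments(m[, batch == b, drop = FALSE]))
  names(moments) <- ub
  # target scale: within-batch variance pooled across batches (batch-centered),
  # NOT the total variance — the total includes the between-batch mean
  # separation and would inflate every batch's spread by the very effect
  # being removed
  w <- vapply(ub, function(b) sum(batch == b), numeric(1)) / length(batch)
  pooled_sd <- sqrt(Reduce(`+`, Map(function(mo, wt) wt * mo$sd^2,
                                    moments, as.list(w))))
  out <- m
  for (b in ub) {
    idx <- which(batch == b)
    bm <- moments[[b]]
    scale <- ifelse(bm$sd > 0, pooled_sd / bm$sd, 1)
    out[, idx] <- (m[, idx, drop = FALSE] - bm$mean) * scale + pooled_mean
  }
  out
}

# ---- adjuster registry -----------------------------------------------------

.adjusters <- new.env(parent = emptyenv())

#' Register, list and retrieve batch adjusters
#'
#' An adjuster is a function `(expr, batch, group) -> expr` that returns a
#' matrix with the same gene and sample roster. Registered adjusters are
#' addressable by name from [adjust_and_rescore()] and the command-line
#' interface; the built-ins are `"identity"` (no change) and
#' `"location_scale"` ([adjust_location_scale()]). The registry exists so
#' external methods (e.g. empirical-Bayes or factor-based adjusters from
#' other packages) can be benchmarked through the same interface without
#' being reimplemented here.
#'
#' @param name Adjuster name.
#' @param fn Function `(expr, batch, group) -> expr`.
#' @param overwrite Allow replacing an existing registration? Default `FALSE`.
#' @return `register_adjuster()` returns `name` invisibly; `list_adjusters()`
#'   the sorted registered names; `get_adjuster()` the function.
#' @export
register_adjuster <- function(name, fn, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.function(fn)) stop("fn must be a function(expr, batch, group)")
  if (!overwrite && !is.null(.adjusters[[name]])) {
    stop("adjuster already registered: ", name)
  }
  assign(name, fn, envir = .adjusters)
  invisible(name)
}

#' @rdname register_adjuster
#' @export
list_adjusters <- function() {
  sort(ls(envir = .adjusters))
}

#' @rdname register_adjuster
#' @export
get_adjuster <- function(name) {
  fn <- .adjusters[[name]]
  if (is.null(fn)) {
    stop("unknown adjuster '", name, "'; registered: ",
         paste(list_adjusters(), collapse = ", "))
  }
  fn
}

#' Oracle adjuster: restore the exact clean matrix
#'
#' Returns an adjuster that ignores its input and yields the clean matrix —
#' equivalent to subtracting the exact injected noise. Useful as the upper
#' bound when benchmarking real adjusters.
#'
#' @param expr_clean The clean genes x samples matrix.
#' @return An adjuster function suitable for [register_adjuster()] or
#'   [adjust_and_rescore()].
#' @export
oracle_adjuster <- function(expr_clean) {
  force(expr_clean)
  function(expr, batch, group = NULL) {
    expr_clean[rownames(expr), colnames(expr), drop = FALSE]
  }
}

.register_builtin_adjusters <- function() {
  if (is.null(.adjusters[["identity"]])) {
    register_adjuster("identity", function(expr, batch, group = NULL) expr)
  }
  if (is.null(.adjusters[["location_scale"]])) {
    register_adjuster("location_scale", function(expr, batch, group = NULL) {
      adjust_location_scale(expr, batch, group,
                            preserve_groups = !is.null(group))
    })
  }
}
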