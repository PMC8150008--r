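#' Fit a sampling-propensity model between two samples
#'
#' Estimates the sampling propensity score s(X) = Pr(Z = 1 | X) — the
#' probability that a row belongs to the focal sample rather than the previous
#' sample — by logistic regression of the membership indicator on the shared
#' covariates, with intercept. When the two samples are (near-)perfectly
#' separated the ordinary ML fit diverges; dissimilarity that extreme is a
#' legitimate, informative outcome, so the model is refit with a small L2
#' (ridge) penalty instead of failing, with a warning. Rank-deficient
#' covariate sets have their collinear columns dropped, with a warning.
#'
#' @param x_focal Matrix or data frame of focal-sample covariates (n_f x p).
#' @param x_prev Matrix or data frame of previous-sample covariates (n_p x p).
#' @param clip Scores are clipped into `[clip, 1 - clip]`.
#' @param ridge Penalty used by the separation fallback (on the standardized
#'   IRLS scale).
#' @return An object of class `swip_propensity`: list with `s_focal`,
#'   `s_prev` (fitted probabilities, clipped), `coef`, and `penalized`
#'   (logical, TRUE when the ridge fallback was used).
#' @export
#' @examples
#' a <- matrix(rnorm(200), 100, 2)
#' b <- matrix(rnorm(200, 1), 100, 2)
#' ps <- fit_propensity(a, b)
#' range(ps$s_focal)
fit_propensity <- function(x_focal, x_prev, clip = 1e-6, ridge = 1e-3) {
  Xf <- as.matrix(x_focal)
  Xp <- as.matrix(x_prev)
  if (nrow(Xf) == 0L || nrow(Xp) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (ncol(Xf) != ncol(Xp)) {
    stop("samples must share the same covariates", call. = FALSE)
  }
  X <- rbind(Xf, Xp)
  if (nrow(X) < ncol(X) + 2L) {
    stop("too few rows to fit the propensity model", call. = FALSE)
  }
  z <- rep(c(1, 0), c(nrow(Xf), nrow(Xp)))

  # drop collinear columns
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    keep <- setdiff(keep, 1L) - 1L
    warning("dropping collinear covariate columns: ",
            paste(setdiff(seq_len(ncol(X)), keep), collapse = ", "),
            call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }

  separated <- FALSE
  fit <- withCallingHandlers(
    glm.fit(cbind(1, X), z, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated || !fit$converged) {
    warning("(near-)separation detected; using ridge-penalized logistic fit",
            call. = FALSE)
    beta <- ridge_logistic(cbind(1, X), z, lambda = ridge)
  } else {
    beta <- fit$coefficients
  }
  s <- plogis(as.numeric(cbind(1, X) %*% beta))
  s <- pmin(pmax(s, clip), 1 - clip)
  structure(
    list(s_focal = s[z == 1], s_prev = s[z == 0],
         coef = beta, penalized = separated || !fit$converged),
    class = "swip_propensity"
  )
}

# L2-penalized logistic regression by IRLS; the intercept is not penalized.
ridge_logistic <- function(X, z, lambda = 1e-3, max_iter = 100, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)), p) * nrow(X)
  beta <- numeric(p)
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zz <- eta + (z - mu) / w
    new <- solve(crossprod(X * sqrt(w)) + pen, crossprod(X, w * zz))
    if (max(abs(new - beta)) < tol) {
      beta <- as.numeric(new)
      break
    }
    beta <- as.numeric(new)
  }
  beta
}

#' Distributional overlap of two score samples
#'
#' Estimates the generalizability index B between two samples of
#' (propensity) scores as the Bhattacharyya coefficient of their densities,
#' B = integral of sqrt(f_a(s) f_b(s)) ds. Each density is estimated by a
#' Gaussian-kernel KDE with an automatic plug-in bandwidth
#' (Sheather-Jones; Silverman's rule for samples too small or too discrete
#' for the plug-in selector), evaluated on a fixed fine grid over `support`,
#' renormalized to integrate to 1 on the grid, and integrated by trapezoidal
#' quadrature. B is 1 for identical distributions and 0 for disjoint ones.
#'
#' The literal product form `integral of f_a f_b` is available via
#' `form = "product"`; it does not reach 1 under perfect similarity and is
#' off by default.
#'
#' @param s_a,s_b Numeric score samples (non-empty).
#' @param support Length-2 finite interval on which densities are compared.
#' @param n_grid Number of evaluation points.
#' @param bw Bandwidth selector: "sj" (plug-in, default), "nrd0" (Silverman),
#'   or a positive number.
#' @param form "bhattacharyya" (default) or "product".
#' @return A scalar in `[0, 1]` (Bhattacharyya form).
#' @export
#' @examples
#' s <- runif(500)
#' overlap_coefficient(s, s) # 1
overlap_coefficient <- function(s_a, s_b, support = c(0, 1), n_grid = 512,
                                bw = "sj",
                                form = c("bhattacharyya", "product")) {
  form <- match.arg(form)
  if (length(s_a) == 0L || length(s_b) == 0L) {
    stop("score samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(support)) || length(support) != 2L) {
    stop("`support` must be a finite interval", call. = FALSE)
  }
  grid <- seq(support[1], support[2], length.out = n_grid)
  fa <- grid_density(s_a, grid, bw)
  fb <- grid_density(s_b, grid, bw)
  val <- if (form == "bhattacharyya") {
    trapz(grid, sqrt(fa * fb))
  } else {
    trapz(grid, fa * fb)
  }
  min(max(val, 0), 1)
}

# Gaussian KDE evaluated on a fixed grid and renormalized to unit mass there.
grid_density <- function(s, grid, bw = "sj") {
  h <- select_bandwidth(s, bw)
  d <- density(s, bw = h, kernel = "gaussian",
               from = grid[1], to = grid[length(grid)], n = length(grid))
  f <- d$y
  mass <- trapz(grid, f)
  if (mass <= 0) {
    # all kernel mass outside the support: tiny uniform floor
    return(rep(1 / (grid[length(grid)] - grid[1]), length(grid)))
  }
  f / mass
}

select_bandwidth <- function(s, bw) {
  if (is.numeric(bw)) {
    if (bw <= 0) stop("numeric `bw` must be positive", call. = FALSE)
    return(bw)
  }
  if (sd(s) < .Machine$double.eps) {
    warning("degenerate (zero-variance) score sample; using minimal bandwidth",
            call. = FALSE)
    return(1e-4)
  }
  h <- switch(bw,
    sj = tryCatch(stats::bw.SJ(s), error = function(e) stats::bw.nrd0(s)),
    nrd0 = stats::bw.nrd0(s),
    stop("unknown bandwidth selector: ", bw, call. = FALSE)
  )
  max(h, 1e-6)
}

#' Average generalizability index between a focal study and a database
#'
#' For each previous study k, fits the sampling-propensity model between the
#' focal predictors and that study's predictors and computes the
#' Bhattacharyya overlap B_k of the two propensity-score densities on
#' `[0, 1]`. B-bar is the unweighted mean of the B_k. The outcome variable is
#' not part of the propensity covariates.
#'
#' @param focal Focal-study tibble (columns `y`, `x1`..`xp`).
#' @param db A `swip_database` from [simulate_database()], or a tibble of
#'   stacked previous studies with a `study_id` column.
#' @param ... Passed on to [overlap_coefficient()].
#' @return An object of class `swip_bbar`: list with `per_study` (tibble
#'   `study_id`, `B`, `penalized`) and `b_bar` (their mean).
#' @export
#' @examples
#' params <- sim_params()
#' cond <- sim_grid(levels_k = 3, levels_dn = 0, levels_dmu = 0.25,
#'                  levels_tau2 = 0.05)[1, ]
#' focal <- simulate_focal(params, seed = 1)
#' db <- simulate_database(cond, params, seed = 2)
#' generalizability_index(focal, db)
generalizability_index <- function(focal, db, ...) {
  studies <- if (inherits(db, "swip_database")) db$studies else db
  stopifnot("study_id" %in% names(studies))
  Xf <- predictor_matrix(focal)
  if (!identical(predictor_cols(focal), predictor_cols(studies))) {
    stop("focal and previous studies must share predictor columns",
         call. = FALSE)
  }
  per <- studies |>
    dplyr::group_by(.data$study_id) |>
    dplyr::group_map(function(d, key) {
      ps <- fit_propensity(Xf, as.matrix(d[predictor_cols(studies)]))
      tibble::tibble(
        study_id = key$study_id,
        B = overlap_coefficient(ps$s_focal, ps$s_prev, support = c(0, 1), ...),
        penalized = ps$penalized
      )
    }) |>
    dplyr::bind_rows()
  structure(list(per_study = per, b_bar = mean(per$B)), class = "swip_bbar")
}

#' @export
print.swip_bbar <- function(x, ...) {
  cat(sprintf("<swip_bbar> B-bar = %.4f over %d studies\n",
              x$b_bar, nrow(x$per_study)))
  print(x$per_study)
  invisible(x)
}
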