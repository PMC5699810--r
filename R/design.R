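#' D-optimality criterion of a coded design matrix
#'
#' Returns `log det(X'X)` for the coded model matrix `X` of a design. A
#' rank-deficient information matrix yields `-Inf` (the "singular"
#' sentinel).
#'
#' @param design Numeric matrix: rows = design points, columns = intercept +
#'   coded main effects.
#' @return Scalar log-determinant, or `-Inf` when singular.
#' @export
d_criterion <- function(design) {
  if (is.null(dim(design))) design <- matrix(design, nrow = 1)
  if (nrow(design) == 0) stop("empty design")
  M <- crossprod(design)
  ld <- determinant(M, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  v <- as.numeric(ld$modulus)
  # determinant() can return a finite value for numerically singular M
  if (qr(M)$rank < ncol(M)) return(-Inf)
  v
}

#' Select a D-optimal subset by Fedorov exchange
#'
#' Greedy best-swap Fedorov exchange: starting from a random size-`n`
#' subset, repeatedly performs the candidate-for-selected swap with the
#' largest increase of `det(X'X)` until no swap improves, and keeps the best
#' of `restarts` random initializations. The swap gain is computed from the
#' classical delta function `d(x_j) - d(x_i) - [d(x_i) d(x_j) - d(x_i,x_j)^2]`
#' with `d(x) = x' M^-1 x`, so each pass costs one matrix inverse.
#'
#' @param candidates Coded candidate matrix (rows = candidate points).
#' @param n Number of points to select (`n <= nrow(candidates)`).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param restarts Number of random initializations.
#' @param max_iter Safety cap on exchange passes per restart.
#' @return List with `row_ids` (selected candidate rows, sorted), `design`
#'   (the selected coded matrix) and `log_det` (criterion value).
#' @export
federov_exchange <- function(candidates, n, seed = 1, restarts = 10,
                             max_iter = 200) {
  X <- as.matrix(candidates)
  m <- nrow(X); p <- ncol(X)
  if (n > m) stop("design infeasible: n exceeds candidate count")
  if (n == m) {
    ld <- d_criterion(X)
    return(list(row_ids = seq_len(m), design = X, log_det = ld))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    sel <- sort(sample.int(m, n))
    sel <- exchange_pass(X, sel, max_iter)
    ld <- d_criterion(X[sel, , drop = FALSE])
    if (is.null(best) || ld > best$log_det + 1e-12) {
      best <- list(row_ids = sort(sel), design = X[sort(sel), , drop = FALSE],
                   log_det = ld)
    }
  }
  if (!is.finite(best$log_det))
    stop("design infeasible: no nonsingular size-n subset found")
  best
}

# one restart: best-swap passes until no improving exchange
exchange_pass <- function(X, sel, max_iter) {
  m <- nrow(X); p <- ncol(X)
  for (iter in seq_len(max_iter)) {
    S <- X[sel, , drop = FALSE]
    M <- crossprod(S)
    # small ridge keeps the pass defined from a singular start; the
    # reported criterion is always the exact determinant
    Minv <- tryCatch(solve(M), error = function(e)
      solve(M + diag(1e-8 * (1 + sum(diag(M)) / p), p)))
    CM <- X %*% Minv
    d_all <- rowSums(CM * X)          # d(x) for every candidate
    A <- S %*% Minv %*% t(X)          # d(x_i, x_j), selected x candidates
    d_sel <- d_all[sel]
    # delta[i, j]: gain from swapping selected i for candidate j
    delta <- outer(rep(1, length(sel)), d_all) -
      matrix(d_sel, length(sel), m) -
      (outer(d_sel, d_all) - A^2)
    delta[, sel] <- -Inf              # candidate already selected
    k <- arrayInd(which.max(delta), dim(delta))
    if (delta[k[1], k[2]] <= 1e-9) break
    sel[k[1]] <- k[2]
  }
  sel
}

#' Code profile variables into a design model matrix
#'
#' Codes the profile + baseline-vital variables for the linear-main-effects
#' design: intercept, continuous variables centered and scaled to [-1, 1]
#' over their schema range, categorical variables as treatment dummies
#' (first level as reference, keeping full column rank).
#'
#' @param profiles data.frame of profile/baseline-vital values.
#' @param schema Schema from [copd_schema()].
#' @return Numeric coded matrix with intercept column.
#' @export
code_profiles <- function(profiles, schema = copd_schema()) {
  sub <- schema[schema$group %in% c("profile", "baseline_vital"), ]
  cols <- list(`(Intercept)` = rep(1, nrow(profiles)))
  for (i in seq_len(nrow(sub))) {
    nm <- sub$name[i]
    x <- profiles[[nm]]
    if (is.null(x)) stop("profiles missing variable '", nm, "'")
    if (sub$kind[i] == "continuous") {
      x <- as.numeric(x)
      mid <- (sub$min[i] + sub$max[i]) / 2
      half <- (sub$max[i] - sub$min[i]) / 2
      cols[[nm]] <- (x - mid) / half
    } else {
      lv <- sub$levels[[i]]
      for (l in lv[-1]) cols[[paste0(nm, "_", l)]] <- as.numeric(x == l)
    }
  }
  do.call(cbind, cols)
}

#' Random candidate set of profile points
#'
#' Draws a diverse candidate set over the design variables (profile +
#' baseline vitals): categorical levels uniform, continuous values uniform
#' over a small grid spanning the schema range (grid points rather than a
#' continuum keep the candidate set in the spirit of a factorial candidate
#' list). Baseline O2 saturation and FEV1 use clinically plausible design
#' ranges rather than the full physiologic range.
#'
#' @param n_candidates Number of candidate profiles.
#' @param seed Integer seed.
#' @param schema Schema from [copd_schema()].
#' @param grid_levels Number of grid levels per continuous variable.
#' @return List with `raw` (data.frame of profile values) and `coded`
#'   (design model matrix from [code_profiles()]).
#' @export
profile_candidates <- function(n_candidates = 1000, seed = 1,
                               schema = copd_schema(), grid_levels = 5) {
  set.seed(seed)
  sub <- schema[schema$group %in% c("profile", "baseline_vital"), ]
  design_range <- list(
    age = c(40, 90), weight = c(90, 350), height = c(58, 78),
    baseline_o2sat = c(82, 99), baseline_fev1 = c(15, 95),
    baseline_heartrate = c(55, 110), baseline_temperature = c(96.5, 99.5)
  )
  raw <- list()
  for (i in seq_len(nrow(sub))) {
    nm <- sub$name[i]
    if (sub$kind[i] == "continuous") {
      rg <- design_range[[nm]]
      grid <- seq(rg[1], rg[2], length.out = grid_levels)
      raw[[nm]] <- sample(grid, n_candidates, replace = TRUE)
    } else {
      raw[[nm]] <- sample(sub$levels[[i]], n_candidates, replace = TRUE)
    }
  }
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  list(raw = raw, coded = code_profiles(raw, schema))
}
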