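## Voxel-wise aperture-weight linear program: assembly, a sparse primal-dual
## interior-point solver specialized to its block structure, slack recovery
## and dose computation.
##
## The LP minimizes
##   OF = pTmax * sum(x_T) + pTmin * sum(y_T) + pOARmax * sum(x_OAR)
## subject to, per target voxel i and prescription map m,
##   sum_j w_j d_ij - x_{i,m} <= Dmax_{i,m} * deltaMax_m
##   sum_j w_j d_ij + y_{i,m} >= Dmin_{i,m} * deltaMin_m
## per OAR voxel i,
##   sum_j w_j d_ij - x_i <= Dcap
## and x, y, w >= 0.

#' LP configuration constructor
#'
#' @param pTmax,pTmin,pOARmax penalties on target overdose, target underdose
#'   and OAR overdose (defaults 1, 1, 0.5).
#' @param tol interior-point convergence tolerance.
#' @param maxIter iteration cap.
#' @param wMax optional soft upper bound on aperture weights.
#' @return an [LPConfig-class].
#' @export
lpConfig <- function(pTmax = 1, pTmin = 1, pOARmax = 0.5, tol = 1e-9,
                     maxIter = 200L, wMax = NA_real_) {
  new("LPConfig", pTmax = pTmax, pTmin = pTmin, pOARmax = pOARmax, tol = tol,
      maxIter = as.integer(maxIter), wMax = wMax)
}

#' Assemble the voxel-wise LP
#'
#' Builds the signed row system from the influence matrix and the robust
#' prescription: two rows (ceiling and floor) per (target voxel, map) pair
#' and one cap row per OAR voxel.  A voxel stacked by k maps therefore
#' carries 2k rows.  Apertures that deposit no dose in any constrained
#' voxel are dropped from the problem (their weight is reported as zero).
#'
#' @param d a [DoseInfluenceMatrix-class].
#' @param rp a [RobustPrescription-class] on the same grid.
#' @param cfg an [LPConfig-class].
#' @return an [LPProblem-class].
#' @export
assembleLP <- function(d, rp, cfg = lpConfig()) {
  validObject(cfg)
  if (!identical(as.integer(d@grid@shape), as.integer(rp@grid@shape)))
    stop("influence matrix and prescription must share the dose grid")
  if (any(Matrix::colSums(d@matrix) == 0))
    stop("assembly error: influence matrix has an all-zero aperture column")
  M <- ncol(d@matrix)
  Gl <- list(); rhs <- list(); pen <- list(); info <- list()
  for (m in seq_along(rp@maps)) {
    map <- rp@maps[[m]]
    vi <- which(map@mask > 0)
    Dm <- d@matrix[vi, , drop = FALSE]
    Gl[[length(Gl) + 1L]] <- Dm
    rhs[[length(rhs) + 1L]] <- map@doseMax[vi] * map@deltaMax
    pen[[length(pen) + 1L]] <- rep(cfg@pTmax, length(vi))
    info[[length(info) + 1L]] <- data.frame(voxel = vi, map = m,
      type = "ceiling", structure = NA_character_)
    Gl[[length(Gl) + 1L]] <- -Dm
    rhs[[length(rhs) + 1L]] <- -(map@doseMin[vi] * map@deltaMin)
    pen[[length(pen) + 1L]] <- rep(cfg@pTmin, length(vi))
    info[[length(info) + 1L]] <- data.frame(voxel = vi, map = m,
      type = "floor", structure = NA_character_)
  }
  for (o in rp@oars) {
    ovi <- which(o@mask@values > 0)
    if (!length(ovi)) next
    Gl[[length(Gl) + 1L]] <- d@matrix[ovi, , drop = FALSE]
    rhs[[length(rhs) + 1L]] <- rep(o@cap, length(ovi))
    pen[[length(pen) + 1L]] <- rep(cfg@pOARmax, length(ovi))
    info[[length(info) + 1L]] <- data.frame(voxel = ovi, map = NA_integer_,
      type = "oar", structure = o@name)
  }
  if (!is.na(cfg@wMax)) {
    Gl[[length(Gl) + 1L]] <- Matrix::Diagonal(M)
    rhs[[length(rhs) + 1L]] <- rep(cfg@wMax, M)
    pen[[length(pen) + 1L]] <- rep(1e6, M)   # soft bound, heavily penalized
    info[[length(info) + 1L]] <- data.frame(voxel = NA_integer_,
      map = NA_integer_, type = "bound", structure = NA_character_)
  }
  G <- do.call(rbind, Gl)
  new("LPProblem", G = G, rhs = unlist(rhs), penalty = unlist(pen),
      rowInfo = do.call(rbind, info), nApertures = as.integer(M),
      grid = rp@grid, config = cfg)
}

setMethod("show", "LPProblem", function(object) {
  tab <- table(object@rowInfo$type)
  cat(sprintf("LPProblem: %d rows (%s), %d aperture weights\n",
              nrow(object@rowInfo),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              object@nApertures))
})

## ---------------------------------------------------------------------------
## Interior-point core
##
## Standard form: variables z = (w [M], p [R], s [R]) >= 0 with
##   [G, -I, I] z = rhs,  minimize penalty' p.
## The normal-equations matrix A D A' = G Dw G' + diag(dp + ds) is inverted
## with the Woodbury identity, reducing every Newton solve to an M x M
## Cholesky (M = apertures), so problem size is limited by rows only
## through O(rows) diagonal work.
## ---------------------------------------------------------------------------

## exact piecewise-linear objective at given weights
.lp_objective <- function(G, rhs, penalty, w) {
  sum(penalty * pmax(as.numeric(G %*% w) - rhs, 0))
}

## solve (E + G Dw G') y = r with the Woodbury identity (an M x M Cholesky)
## plus iterative refinement against the exact operator - the normal
## equations become very ill-conditioned near convergence
.make_adat_solver <- function(G, dw, e) {
  Ei <- 1 / e
  S <- as.matrix(Matrix::crossprod(G, G * Ei)) + diag(1 / dw, length(dw))
  Sc <- tryCatch(chol(S), error = function(err)
    chol(S + diag(1e-10 * max(diag(S)), nrow(S))))
  wood <- function(r) {
    a <- Ei * r
    t1 <- as.numeric(Matrix::crossprod(G, a))
    t2 <- backsolve(Sc, backsolve(Sc, t1, transpose = TRUE))
    a - Ei * as.numeric(G %*% t2)
  }
  Mmul <- function(y)
    e * y + as.numeric(G %*% (dw * as.numeric(Matrix::crossprod(G, y))))
  function(r) {
    y <- wood(r)
    rn <- sqrt(sum(r^2))
    for (k in 1:3) {
      res <- r - Mmul(y)
      if (sqrt(sum(res^2)) <= 1e-14 * rn) break
      y <- y + wood(res)
    }
    y
  }
}

## active-set least-squares polish of the weights: repeatedly fit the
## (near-)active rows in a weighted least-squares sense and keep the result
## only when the exact objective decreases; recovers machine-precision
## weights on faces where the interior-point iterate stops at ~sqrt(eps)
.polish_weights <- function(G, rhs, penalty, w) {
  f0 <- .lp_objective(G, rhs, penalty, w)
  tolAct <- 1e-6 * (1 + max(abs(rhs)))
  for (k in 1:5) {
    r <- as.numeric(G %*% w) - rhs
    act <- which(r > -tolAct & penalty > 0)
    if (!length(act)) break
    GA <- G[act, , drop = FALSE]
    P <- penalty[act]
    S <- as.matrix(Matrix::crossprod(GA, GA * P))
    S <- S + diag(1e-10 * max(diag(S), 1), nrow(S))
    b <- as.numeric(Matrix::crossprod(GA, P * rhs[act]))
    wn <- pmax(solve(S, b), 0)
    fn <- .lp_objective(G, rhs, penalty, wn)
    if (fn < f0 * (1 - 1e-12)) {
      w <- wn; f0 <- fn
    } else break
  }
  w
}

## Mehrotra predictor-corrector on the structured standard form.
## Returns list(w, status, iterations, gap)
.ipm_solve <- function(G, rhs, penalty, tol = 1e-9, maxIter = 200L) {
  R <- nrow(G); M <- ncol(G)
  n <- M + 2L * R
  c_ <- c(numeric(M), penalty, numeric(R))
  bnorm <- 1 + sqrt(sum(rhs^2)); cnorm <- 1 + sqrt(sum(c_^2))
  Amul <- function(w, p, s) as.numeric(G %*% w) - p + s
  Atmul <- function(lam) list(w = as.numeric(Matrix::crossprod(G, lam)),
                              p = -lam, s = lam)
  ## starting point (least-squares heuristic)
  solver0 <- .make_adat_solver(G, rep(1, M), rep(2, R))
  xlam <- solver0(rhs)
  At0 <- Atmul(xlam)
  x <- c(At0$w, At0$p, At0$s)
  lam <- solver0(-penalty)   # A c = -penalty (c has zeros on w and s)
  Atl <- Atmul(lam)
  zs <- c_ - c(Atl$w, Atl$p, Atl$s)
  x <- x + max(-1.5 * min(x), 0)
  zs <- zs + max(-1.5 * min(zs), 0)
  xz <- sum(x * zs)
  x <- x + 0.5 * xz / max(sum(zs), 1e-12)
  zs <- zs + 0.5 * xz / max(sum(x), 1e-12)
  x <- pmax(x, 1e-8); zs <- pmax(zs, 1e-8)
  iw <- seq_len(M); ip <- M + seq_len(R); is_ <- M + R + seq_len(R)
  status <- "max-iterations"; it <- 0L; mu <- sum(x * zs) / n
  best <- x; bestScore <- Inf; bestMu <- mu
  for (it in seq_len(maxIter)) {
    rb <- Amul(x[iw], x[ip], x[is_]) - rhs
    Atl <- Atmul(lam)
    rc <- c(Atl$w, Atl$p, Atl$s) + zs - c_
    mu <- sum(x * zs) / n
    obj <- sum(c_ * x)
    pinf <- sqrt(sum(rb^2)) / bnorm
    dinf <- sqrt(sum(rc^2)) / cnorm
    score <- mu / (1 + abs(obj)) + pinf + dinf
    if (score < bestScore) { bestScore <- score; best <- x; bestMu <- mu }
    if (mu / (1 + abs(obj)) < tol && pinf < 1e-8 && dinf < 1e-8) {
      status <- "optimal"; break
    }
    ## numerical blow-up guard: the Newton system eventually becomes too
    ## ill-conditioned; return the best iterate (then polished)
    if (score > 1e4 * bestScore + 1e-12) { status <- "stalled"; break }
    d <- pmin(pmax(x / zs, 1e-10), 1e10)
    solver <- .make_adat_solver(G, d[iw], d[ip] + d[is_])
    newton <- function(rxs) {
      ## rhs of normal equations: -rb - A (D rc - ZS^{-1} rxs)
      t_ <- d * rc - rxs / zs
      rhsN <- -rb - (as.numeric(G %*% t_[iw]) - t_[ip] + t_[is_])
      dlam <- solver(rhsN)
      Atd <- Atmul(dlam)
      dzs <- -rc - c(Atd$w, Atd$p, Atd$s)
      dx <- -d * dzs - rxs / zs
      list(dx = dx, dlam = dlam, dzs = dzs)
    }
    aff <- newton(x * zs)
    alphaP <- function(v, dv) {
      neg <- which(dv < 0)
      if (!length(neg)) 1 else min(1, min(-v[neg] / dv[neg]))
    }
    apri <- alphaP(x, aff$dx); adua <- alphaP(zs, aff$dzs)
    muAff <- sum((x + apri * aff$dx) * (zs + adua * aff$dzs)) / n
    sigma <- min(1, muAff / mu)^3
    rxs <- x * zs + aff$dx * aff$dzs - sigma * mu
    cc <- newton(rxs)
    eta <- 1 - min(0.005, max(mu, 1e-8))
    apri <- min(1, eta * alphaP(x, cc$dx))
    adua <- min(1, eta * alphaP(zs, cc$dzs))
    x <- x + apri * cc$dx
    lam <- lam + adua * cc$dlam
    zs <- zs + adua * cc$dzs
  }
  if (status != "optimal") {
    x <- best; mu <- bestMu
    ## safeguarded convergence: accept the best iterate when it met a
    ## slightly looser version of the stopping test
    if (bestScore < 1e-6) status <- "optimal"
    else if (status == "stalled") status <- "max-iterations"
  }
  w <- .polish_weights(G, rhs, penalty, pmax(x[iw], 0))
  list(w = w, status = status, iterations = it, gap = mu)
}

#' Solve the voxel-wise LP
#'
#' Runs the structured interior-point method on an assembled problem and
#' returns aperture weights, per-row slacks, the objective value and the
#' planned dose.  With free slack variables the LP is always feasible and
#' the objective is bounded below by zero, so the only failure mode is
#' non-convergence, surfaced as status \code{"max-iterations"}.
#'
#' @param problem an [LPProblem-class].
#' @param d the [DoseInfluenceMatrix-class] used at assembly (for the dose
#'   reconstruction).
#' @param warmWeights optional feasible weight vector (e.g. a prior plan);
#'   kept whenever the solver does not improve on it.
#' @return an [LPSolution-class].
#' @examples
#' ## one voxel, one aperture, unit influence, 70 Gy band -> w = 70, OF = 0
#' @export
## build an LPSolution for given weights: per-row violations, objective,
## planned dose
.solution_from_weights <- function(problem, d, w, status, iterations, gap) {
  doseVec <- as.numeric(d@matrix %*% w)
  gw <- as.numeric(problem@G %*% w)
  viol <- pmax(gw - problem@rhs, 0)
  typ <- problem@rowInfo$type
  over <- ifelse(typ %in% c("ceiling", "oar", "bound"), viol, 0)
  under <- ifelse(typ == "floor", viol, 0)
  dose <- imageVolume(array(doseVec, dim = problem@grid@shape),
                      problem@grid, "dose-Gy")
  new("LPSolution", weights = w, overdose = over, underdose = under,
      objective = sum(problem@penalty * viol), status = status,
      iterations = as.integer(iterations), gap = gap, dose = dose,
      problem = problem)
}

solveLP <- function(problem, d, warmWeights = NULL) {
  cfg <- problem@config
  ## apertures depositing nothing in any constrained voxel are free
  ## variables of the LP; fix their weight at zero and solve the rest
  live <- which(Matrix::colSums(problem@G != 0) > 0)
  if (!length(live)) stop("no aperture influences any constrained voxel")
  res <- .ipm_solve(problem@G[, live, drop = FALSE], problem@rhs,
                    problem@penalty, tol = cfg@tol, maxIter = cfg@maxIter)
  w <- numeric(problem@nApertures)
  w[live] <- pmax(res$w, 0)
  w[w < 1e-10 * max(w)] <- 0
  ## a caller-supplied feasible point (e.g. the prior plan in adaptive
  ## replanning) can only be replaced by something at least as good
  if (!is.null(warmWeights) &&
      .lp_objective(problem@G, problem@rhs, problem@penalty, warmWeights) <
      .lp_objective(problem@G, problem@rhs, problem@penalty, w))
    w <- warmWeights
  .solution_from_weights(problem, d, w, res$status, res$iterations, res$gap)
}

#' @export
setMethod("weights", "LPSolution", function(object, ...) object@weights)

#' @export
setMethod("plannedDose", "LPSolution", function(x) x@dose)

#' @export
setMethod("objectiveValue", "LPSolution", function(x) x@objective)

setMethod("show", "LPSolution", function(object) {
  cat(sprintf(
    "LPSolution [%s]: OF = %.6g, %d apertures (%d active), %d iterations\n",
    object@status, object@objective, length(object@weights),
    sum(object@weights > 0), object@iterations))
})

#' Analytic slack recovery (the solver's independent oracle)
#'
#' For fixed aperture weights the optimal slack variables have a closed
#' form: overdose x = max(0, dose - ceiling), underdose y = max(0, floor -
#' dose), and the objective follows from the penalties.  This recomputes
#' all of them directly from the influence matrix and the prescription,
#' bypassing the LP assembly entirely.
#'
#' @param w aperture weights (>= 0).
#' @param d a [DoseInfluenceMatrix-class].
#' @param rp a [RobustPrescription-class].
#' @param cfg an [LPConfig-class] (penalties).
#' @return data.frame with one row per constraint (voxel, map, type,
#'   structure, bound, dose, slack); the objective value is attached as
#'   attribute \code{"objective"}.
#' @export
recoverSlacks <- function(w, d, rp, cfg = lpConfig()) {
  stopifnot(all(w >= 0))
  doseVec <- as.numeric(d@matrix %*% w)
  rows <- list(); of <- 0
  for (m in seq_along(rp@maps)) {
    map <- rp@maps[[m]]
    vi <- which(map@mask > 0)
    dv <- doseVec[vi]
    x <- pmax(0, dv - map@doseMax[vi] * map@deltaMax)
    y <- pmax(0, map@doseMin[vi] * map@deltaMin - dv)
    rows[[length(rows) + 1L]] <- data.frame(voxel = vi, map = m,
      type = "ceiling", structure = NA_character_,
      bound = map@doseMax[vi] * map@deltaMax, dose = dv, slack = x)
    rows[[length(rows) + 1L]] <- data.frame(voxel = vi, map = m,
      type = "floor", structure = NA_character_,
      bound = map@doseMin[vi] * map@deltaMin, dose = dv, slack = y)
    of <- of + cfg@pTmax * sum(x) + cfg@pTmin * sum(y)
  }
  for (o in rp@oars) {
    ovi <- which(o@mask@values > 0)
    if (!length(ovi)) next
    dv <- doseVec[ovi]
    x <- pmax(0, dv - o@cap)
    rows[[length(rows) + 1L]] <- data.frame(voxel = ovi, map = NA_integer_,
      type = "oar", structure = o@name, bound = o@cap, dose = dv, slack = x)
    of <- of + cfg@pOARmax * sum(x)
  }
  out <- do.call(rbind, rows)
  attr(out, "objective") <- of
  out
}

#' Dose from aperture weights
#'
#' @param d a [DoseInfluenceMatrix-class].
#' @param w aperture weights.
#' @return a \code{"dose-Gy"} [ImageVolume-class] on the dose grid.
#' @export
computeDose <- function(d, w) {
  if (length(w) != ncol(d@matrix))
    stop("dimension mismatch: ", length(w), " weights for ",
         ncol(d@matrix), " apertures")
  imageVolume(array(as.numeric(d@matrix %*% w), dim = d@grid@shape),
              d@grid, "dose-Gy")
}
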