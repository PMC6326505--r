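## Shared fixture builders and independent oracles.  Everything is built in
## code at test time; no data files.

## tiny influence matrix straight from a dense matrix
mkInfluence <- function(mat, grid) {
  new("DoseInfluenceMatrix",
      matrix = methods::as(Matrix::Matrix(mat, sparse = TRUE),
                           "CsparseMatrix"),
      grid = grid, apertures = as.list(seq_len(ncol(mat))))
}

## single-map robust prescription on an n x 1 x 1 grid
mkRx <- function(grid, mask, dose, dmin = dose, dmax = dose,
                 delta = c(1, 1), oars = list()) {
  sh <- grid@shape
  map <- new("PrescriptionMap", grid = grid,
             mask = array(mask, sh), dose = array(dose, sh),
             doseMin = array(dmin, sh), doseMax = array(dmax, sh),
             deltaMin = delta[1L], deltaMax = delta[2L], label = "dpbn")
  nT <- as.integer(sum(mask > 0))
  nO <- if (length(oars))
    sum(Reduce(`|`, lapply(oars, function(o) o@mask@values > 0))) else 0L
  new("RobustPrescription", grid = grid, maps = list(map), oars = oars,
      unionMask = array((mask > 0) * 1, sh), nT = nT,
      n = as.integer(nT + nO))
}

lineGrid <- function(n) gridSpecNew(c(n, 1, 1), c(1, 1, 1))

## exact planning objective at given weights (independent arithmetic)
lpObjectiveAt <- function(w, d, rp, cfg = lpConfig()) {
  attr(recoverSlacks(w, d, rp, cfg), "objective")
}

## brute-force LP minimization by vertex enumeration of the hyperplane
## arrangement {rows of G} union {w_k = 0}: for a coercive piecewise-linear
## convex objective the minimum is attained at one of these vertices
bruteForceLP <- function(G, rhs, penalty) {
  Gd <- as.matrix(G)
  M <- ncol(Gd)
  planes <- rbind(Gd, diag(M))
  prhs <- c(rhs, numeric(M))
  fv <- function(w) sum(penalty * pmax(as.numeric(Gd %*% w) - rhs, 0))
  best <- Inf
  for (comb in utils::combn(nrow(planes), M, simplify = FALSE)) {
    A <- planes[comb, , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    w <- tryCatch(solve(A, prhs[comb]), error = function(e) NULL)
    if (is.null(w) || any(w < -1e-9)) next
    best <- min(best, fv(pmax(w, 0)))
  }
  best
}

## brute-force 26-connected component labelling by breadth-first search
bfsComponents <- function(fg) {
  d <- dim(fg)
  lab <- array(0L, dim = d)
  nxt <- 0L
  idx <- which(fg)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in idx) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      k <- (v - 1L) %/% (d[1L] * d[2L]) + 1L
      r <- (v - 1L) %% (d[1L] * d[2L])
      j <- r %/% d[1L] + 1L
      i <- r %% d[1L] + 1L
      for (o in seq_len(nrow(offs))) {
        ii <- i + offs[o, 1L]; jj <- j + offs[o, 2L]; kk <- k + offs[o, 3L]
        if (ii < 1L || ii > d[1L] || jj < 1L || jj > d[2L] ||
            kk < 1L || kk > d[3L]) next
        w <- ii + (jj - 1L) * d[1L] + (kk - 1L) * d[1L] * d[2L]
        if (fg[w] && lab[w] == 0L) {
          lab[w] <- nxt
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

## small uniform-SUV sphere volume for segmentation tests
sphereSUV <- function(radius = 6, level = 10, spacing = c(2, 2, 2),
                      half = 16) {
  g <- gridCovering(rep(-half, 3), rep(half, 3), spacing)
  les <- lesionSpec("S", "sphere", c(0, 0, 0), radius, activity = level)
  makeActivityTruth(list(les), g)
}
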