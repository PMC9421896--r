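# Analysis of steered trajectories: binned profiles, break-force correction,
# bond- and contact-fraction curves, peak detection, Kabsch RMSD,
# representative conformers, structural descriptors and breaking order.

.asTrajList <- function(trajectories) {
  if (is(trajectories, "SMDTrajectory")) list(trajectories)
  else trajectories
}

#' Bin pulling force against extension
#'
#' Pools every saved observation of every trajectory into fixed-width
#' extension bins and reports the per-bin mean force and standard error of
#' the mean (sample sd / sqrt(n)).  Bins without observations are absent
#' from the result, not zero.
#'
#' @param trajectories an \code{SMDTrajectory} or list of them (or a
#'   data.frame with columns \code{extension_A} and \code{force_pN}).
#' @param binWidth bin width, A.
#' @return a \code{ForceExtensionProfile}.
#' @export
binForceExtension <- function(trajectories, binWidth = 1.0) {
  if (is.data.frame(trajectories)) {
    df <- trajectories
  } else {
    trajectories <- .asTrajList(trajectories)
    if (length(trajectories) == 0) stop("need at least one trajectory")
    df <- do.call(rbind, lapply(trajectories, function(t)
      t@log[, c("extension_A", "force_pN")]))
  }
  if (nrow(df) == 0) stop("no observations to bin")
  stopifnot(all(is.finite(df$extension_A)), all(is.finite(df$force_pN)))
  bin <- floor(df$extension_A / binWidth)
  agg <- lapply(split(df$force_pN, bin), function(v)
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0))
  b <- as.numeric(names(agg))
  m <- do.call(rbind, agg)
  ord <- order(b)
  prof <- data.frame(bin_lo = b[ord] * binWidth,
                     bin_hi = (b[ord] + 1) * binWidth,
                     mid = (b[ord] + 0.5) * binWidth,
                     n = m[ord, "n"], mean_force_pN = m[ord, "mean"],
                     sem_pN = m[ord, "sem"])
  rownames(prof) <- NULL
  new("ForceExtensionProfile", profile = prof, binWidth = binWidth)
}

#' Subtract the constant restraint tail force after bond breaking
#'
#' In restraint mode each broken pair keeps pulling on the chain with the
#' constant linear-tail force 2 k (r3 - r2); once a pair has permanently
#' entered the tail (its final break event), that force is subtracted from
#' all subsequent spring-force readings.
#'
#' @param trajectory an \code{SMDTrajectory} from a restraint-mode run.
#' @param forcePN tail force per broken pair, pN; default from the
#'   trajectory's restraint constants (555.8 pN with the published values).
#' @param restraint \code{RestraintParams} used to compute the default.
#' @return the trajectory with a corrected force column.
#' @export
subtractBreakForce <- function(trajectory, forcePN = NULL,
                               restraint = RestraintParams()) {
  if (trajectory@mode != "restraint")
    stop("break-force subtraction applies to restraint-mode trajectories only")
  if (is.null(forcePN))
    forcePN <- forceToPN(2 * restraint@k * (restraint@r3 - restraint@r2))
  ev <- trajectory@events
  log <- trajectory@log
  if (nrow(ev) > 0) {
    brk <- ev[ev$kind == "break", , drop = FALSE]
    if (nrow(brk) > 0) {
      key <- paste(brk$resi, brk$resj)
      finalStep <- vapply(split(brk$step, key), max, numeric(1))
      for (s in finalStep)
        log$force_pN[log$step >= s] <- log$force_pN[log$step >= s] - forcePN
    }
  }
  out <- trajectory
  out@log <- log
  out
}

#' Disulfide bond fraction against extension
#'
#' Per extension bin and per monitored cysteine pair (native and non-native
#' alike), the fraction of observations whose side-center (C-beta proxy)
#' distance is below the cutoff.
#'
#' @param trajectories an \code{SMDTrajectory} or list of them.
#' @param pairs optional two-column matrix of 1-based residue pairs to
#'   restrict to; default all monitored pairs.
#' @param cutoff bond-presence cutoff, A.
#' @param binWidth bin width, A.
#' @return data.frame: \code{mid}, \code{resi}, \code{resj}, \code{label},
#'   \code{native}, \code{n}, \code{fraction}.
#' @export
bondFractionVsExtension <- function(trajectories, pairs = NULL, cutoff = 5.5,
                                    binWidth = 1.0) {
  trajectories <- .asTrajList(trajectories)
  stopifnot(length(trajectories) > 0)
  ref <- trajectories[[1]]@pairs
  sel <- seq_len(nrow(ref))
  if (!is.null(pairs)) {
    pairs <- matrix(pairs, ncol = 2)
    sel <- vapply(seq_len(nrow(pairs)), function(q) {
      hit <- which((ref$resi == pairs[q, 1] & ref$resj == pairs[q, 2]) |
                   (ref$resi == pairs[q, 2] & ref$resj == pairs[q, 1]))
      if (length(hit) == 0) stop(sprintf("unknown pair %d-%d",
                                         pairs[q, 1], pairs[q, 2]))
      hit[1]
    }, integer(1))
  }
  out <- NULL
  for (q in sel) {
    ext <- unlist(lapply(trajectories, function(t) t@log$extension_A))
    bnd <- unlist(lapply(trajectories, function(t) t@pairDist[, q] < cutoff))
    bin <- floor(ext / binWidth)
    frac <- vapply(split(bnd, bin), mean, numeric(1))
    n <- vapply(split(bnd, bin), length, numeric(1))
    b <- as.numeric(names(frac))
    out <- rbind(out, data.frame(
      mid = (b + 0.5) * binWidth, resi = ref$resi[q], resj = ref$resj[q],
      label = sprintf("%d-%d", ref$resi[q], ref$resj[q]),
      native = ref$native[q], n = n, fraction = frac))
  }
  out <- out[order(out$label, out$mid), ]
  rownames(out) <- NULL
  out
}

#' Native-contact fraction per structural element against extension
#'
#' For each saved frame, the fraction of each element's native contacts
#' whose distance is within \code{tol} times the native distance, binned by
#' extension.  This is the secondary-structure proxy of the coarse-grained
#' model.  Elements with zero contacts are excluded with a warning.
#'
#' @param trajectories an \code{SMDTrajectory} or list of them (coordinates
#'   must have been kept).
#' @param topology the \code{ChainTopology} the runs used.
#' @param tol contact-intact tolerance (fraction of native distance).
#' @param binWidth bin width, A.
#' @return data.frame: \code{mid}, \code{element}, \code{n}, \code{fraction}.
#' @export
contactFractionByElement <- function(trajectories, topology, tol = 1.2,
                                     binWidth = 1.0) {
  trajectories <- .asTrajList(trajectories)
  nc <- topology@nativeContacts
  if (nrow(nc) == 0) stop("topology has no native contacts")
  # per-residue elements only (interface contacts keep their joint label)
  els <- sort(unique(nc$element))
  counts <- table(nc$element)
  empty <- setdiff(unique(topology@elements$element), names(counts))
  if (length(empty) > 0)
    warning("elements without native contacts excluded: ",
            paste(empty, collapse = ", "))
  out <- NULL
  for (tr in trajectories) {
    if (length(tr@coords) == 0)
      stop("trajectory was run with keepCoords = FALSE")
    nf <- dim(tr@coords)[3]
    ii <- nc$i + 1L; jj <- nc$j + 1L
    fracs <- matrix(NA_real_, nf, length(els),
                    dimnames = list(NULL, els))
    for (f in seq_len(nf)) {
      x <- t(tr@coords[, , f])
      d <- sqrt(rowSums((x[ii, , drop = FALSE] - x[jj, , drop = FALSE])^2))
      ok <- d < tol * nc$r0
      fracs[f, ] <- vapply(els, function(e) mean(ok[nc$element == e]),
                           numeric(1))
    }
    out <- rbind(out, data.frame(extension = tr@log$extension_A,
                                 fracs, check.names = FALSE))
  }
  bin <- floor(out$extension / binWidth)
  res <- NULL
  for (e in els) {
    frac <- vapply(split(out[[e]], bin), mean, numeric(1))
    n <- vapply(split(out[[e]], bin), length, numeric(1))
    b <- as.numeric(names(frac))
    res <- rbind(res, data.frame(mid = (b + 0.5) * binWidth, element = e,
                                 n = n, fraction = frac))
  }
  rownames(res) <- NULL
  res
}

#' Detect force peaks in a binned profile
#'
#' Moving-average smoothing followed by a local-extremum scan; extrema whose
#' prominence falls below the threshold are discarded (smallest first), so
#' maxima and minima alternate in the result.  Deterministic.
#'
#' @param profile a \code{ForceExtensionProfile}.
#' @param window smoothing window, bins (odd).
#' @param prominence minimum peak prominence, pN; default twice the median
#'   per-bin standard error.
#' @return data.frame: \code{extension_A}, \code{force_pN}, \code{kind}
#'   ("maximum"/"minimum").
#' @export
detectPeaks <- function(profile, window = 5L,
                        prominence = 2 * median(profile@profile$sem_pN)) {
  p <- profile@profile
  empty <- data.frame(extension_A = numeric(0), force_pN = numeric(0),
                      kind = character(0))
  if (nrow(p) < 3) return(empty)
  y <- p$mean_force_pN
  half <- window %/% 2
  sm <- vapply(seq_along(y), function(i)
    mean(y[max(1, i - half):min(length(y), i + half)]), numeric(1))
  # alternating extrema of the smoothed series
  idx <- integer(0); kind <- character(0)
  dy <- diff(sm)
  s <- sign(dy); s[s == 0] <- NA
  s <- .fillSign(s)
  turn <- which(diff(s) != 0) + 1L
  for (t in turn) {
    idx <- c(idx, t)
    kind <- c(kind, if (s[t] < s[t - 1]) "maximum" else "minimum")
  }
  if (length(idx) == 0) return(empty)
  # iteratively drop the weakest adjacent extremum pair below the prominence
  repeat {
    if (length(idx) == 0) break
    amp <- abs(diff(c(sm[idx])))
    edgeAmp <- c(abs(sm[idx[1]] - sm[1]),
                 if (length(idx) > 1) amp else numeric(0),
                 abs(sm[length(sm)] - sm[idx[length(idx)]]))
    prom <- vapply(seq_along(idx), function(q)
      min(edgeAmp[q], edgeAmp[q + 1]), numeric(1))
    weakest <- which.min(prom)
    if (prom[weakest] >= prominence) break
    idx <- idx[-weakest]; kind <- kind[-weakest]
    # restore alternation by dropping the weaker of equal neighbours
    q <- 2
    while (q <= length(idx)) {
      if (kind[q] == kind[q - 1]) {
        drop <- if (kind[q] == "maximum") {
          if (sm[idx[q]] >= sm[idx[q - 1]]) q - 1 else q
        } else {
          if (sm[idx[q]] <= sm[idx[q - 1]]) q - 1 else q
        }
        idx <- idx[-drop]; kind <- kind[-drop]
      } else q <- q + 1
    }
  }
  if (length(idx) == 0) return(empty)
  data.frame(extension_A = p$mid[idx], force_pN = p$mean_force_pN[idx],
             kind = kind)
}

# forward-fill NA in a sign vector (interior plateaus)
.fillSign <- function(s) {
  if (all(is.na(s))) return(rep(1, length(s)))
  for (i in seq_along(s)) if (is.na(s[i]) && i > 1) s[i] <- s[i - 1]
  for (i in rev(seq_along(s))) if (is.na(s[i]) && i < length(s)) s[i] <- s[i + 1]
  s
}

#' Minimum-RMSD representative of an extension window
#'
#' Extracts all frames within \code{window} of the target extension, computes
#' the full pairwise Kabsch RMSD table over backbone beads, and returns the
#' frame minimizing the sum of RMSDs to all others (ties broken by the lowest
#' frame id).
#'
#' @param trajectories an \code{SMDTrajectory} or list of them (coordinates
#'   kept).
#' @param extension target extension, A (typically a force minimum).
#' @param window half-width of the extension window, A.
#' @param nBackbone number of backbone beads (default: all residues).
#' @return list with \code{frame} (data.frame: trajectory, frame), the
#'   representative \code{coords} (nBackbone x 3), the \code{rmsdSum} vector
#'   over candidates, and the candidate table.
#' @export
selectRepresentative <- function(trajectories, extension, window = 1.0,
                                 nBackbone = NULL) {
  trajectories <- .asTrajList(trajectories)
  cand <- NULL
  coordsList <- list()
  for (ti in seq_along(trajectories)) {
    tr <- trajectories[[ti]]
    if (length(tr@coords) == 0)
      stop("trajectory was run with keepCoords = FALSE")
    sel <- which(abs(tr@log$extension_A - extension) <= window)
    nb <- if (is.null(nBackbone)) dim(tr@coords)[2] else nBackbone
    for (f in sel) {
      coordsList[[length(coordsList) + 1]] <-
        t(tr@coords[, seq_len(nb), f])
      cand <- rbind(cand, data.frame(trajectory = ti, frame = f))
    }
  }
  if (is.null(cand))
    stop(sprintf("no frames within %.1f A of extension %.1f A",
                 window, extension))
  m <- length(coordsList)
  rmsdSum <- numeric(m)
  if (m > 1) {
    rm <- matrix(0, m, m)
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      r <- kabschRMSD(coordsList[[a]], coordsList[[b]])
      rm[a, b] <- r; rm[b, a] <- r
    }
    rmsdSum <- rowSums(rm)
  }
  best <- which(rmsdSum == min(rmsdSum))[1]
  list(frame = cand[best, ], coords = coordsList[[best]], rmsdSum = rmsdSum,
       candidates = cand)
}

#' Kabsch-superposition RMSD
#'
#' Minimum root-mean-square deviation between two matched coordinate sets
#' over rigid rotations and translations; reflections are disallowed.
#'
#' @param x,y coordinate matrices (n x 3), equal n >= 3.
#' @return RMSD in A.
#' @export
kabschRMSD <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("coordinate size mismatch")
  if (nrow(x) < 3) stop("need at least 3 points")
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  sqrt(max(0, mean(rowSums((yc %*% R - xc)^2))))
}

#' Superpose one coordinate set onto another
#'
#' @param x,y coordinate matrices (n x 3); \code{x} is rotated/translated
#'   onto \code{y}.
#' @return transformed copy of \code{x}.
#' @export
superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(xc %*% R, 2, cy, "+")
}

#' Radius of gyration, maximum radius and per-residue RMSF
#'
#' Rg is the mass-uniform radius of gyration; Rgmax the maximum bead
#' distance from the geometric center.  RMSF is computed per backbone bead
#' about the mean structure after superposition, using only the second half
#' of the frames.
#'
#' @param trajectory an \code{SMDTrajectory} with coordinates kept.
#' @param nBackbone number of backbone beads (default: all residues from the
#'   coordinate array).
#' @return list with per-frame \code{rg}, \code{rgmax} and per-residue
#'   \code{rmsf}.
#' @export
rgRgmaxRmsf <- function(trajectory, nBackbone = NULL) {
  if (length(trajectory@coords) == 0)
    stop("trajectory was run with keepCoords = FALSE")
  nf <- dim(trajectory@coords)[3]
  nb <- if (is.null(nBackbone)) dim(trajectory@coords)[2] else nBackbone
  rg <- numeric(nf); rgmax <- numeric(nf)
  for (f in seq_len(nf)) {
    x <- t(trajectory@coords[, seq_len(nb), f])
    c0 <- colMeans(x)
    d2 <- rowSums(sweep(x, 2, c0)^2)
    rg[f] <- sqrt(mean(d2))
    rgmax[f] <- sqrt(max(d2))
  }
  if (nf < 2) stop("RMSF undefined for a single frame")
  half <- seq(floor(nf / 2) + 1, nf)
  ref <- t(trajectory@coords[, seq_len(nb), half[1]])
  sup <- lapply(half, function(f)
    superpose(t(trajectory@coords[, seq_len(nb), f]), ref))
  meanX <- Reduce(`+`, sup) / length(sup)
  sup <- lapply(sup, function(x) superpose(x, meanX))
  meanX <- Reduce(`+`, sup) / length(sup)
  dev <- vapply(sup, function(x) rowSums((x - meanX)^2), numeric(nb))
  list(rg = rg, rgmax = rgmax, rmsf = sqrt(rowMeans(dev)))
}

#' Consensus disulfide breaking order over an ensemble
#'
#' Per trajectory, each pair's final break extension (reformation before the
#' last break is ignored) defines a rank; pairs that never break rank last
#' as "unbroken".  The ensemble consensus orders pairs by median rank, and
#' per-rank vote counts are reported.
#'
#' @param trajectories an \code{SMDTrajectory} or list of them.
#' @return data.frame ordered by consensus rank: \code{label},
#'   \code{medianRank}, \code{meanFinalBreak_A}, \code{nBroken}, \code{votes}
#'   (rank vote counts as a semicolon string).
#' @export
breakingOrder <- function(trajectories) {
  trajectories <- .asTrajList(trajectories)
  labels <- sprintf("%d-%d", trajectories[[1]]@pairs$resi,
                    trajectories[[1]]@pairs$resj)
  np <- length(labels)
  rankM <- matrix(NA_real_, length(trajectories), np,
                  dimnames = list(NULL, labels))
  extM <- matrix(NA_real_, length(trajectories), np,
                 dimnames = list(NULL, labels))
  for (ti in seq_along(trajectories)) {
    tr <- trajectories[[ti]]
    ev <- tr@events
    fin <- rep(NA_real_, np)
    for (q in seq_len(np)) {
      sel <- ev$kind == "break" & ev$resi == tr@pairs$resi[q] &
             ev$resj == tr@pairs$resj[q]
      if (any(sel)) fin[q] <- max(ev$extension_A[sel])
    }
    # never-broken pairs sort last
    r <- rank(ifelse(is.na(fin), Inf, fin), ties.method = "first")
    r[is.na(fin)] <- NA
    rankM[ti, ] <- r
    extM[ti, ] <- fin
  }
  med <- apply(rankM, 2, function(v) if (all(is.na(v))) Inf
               else median(v, na.rm = TRUE))
  votes <- vapply(seq_len(np), function(q) {
    v <- rankM[, q]
    tab <- table(factor(v[!is.na(v)], levels = seq_len(np)))
    unbroken <- sum(is.na(v))
    paste0(paste(sprintf("r%d:%d", seq_len(np), as.integer(tab)),
                 collapse = ";"),
           if (unbroken > 0) sprintf(";unbroken:%d", unbroken) else "")
  }, character(1))
  out <- data.frame(label = labels, medianRank = med,
                    meanFinalBreak_A = colMeans(extM, na.rm = TRUE),
                    nBroken = colSums(!is.na(extM)), votes = votes)
  out$medianRank[!is.finite(out$medianRank)] <- NA
  out <- out[order(is.na(out$medianRank), out$medianRank,
                   out$meanFinalBreak_A), ]
  rownames(out) <- NULL
  out
}

#' Plot a force-extension profile
#'
#' @param x a \code{ForceExtensionProfile}.
#' @param y ignored.
#' @param ... passed to \code{plot}.
#' @export
setMethod("plot", signature(x = "ForceExtensionProfile", y = "missing"),
          function(x, y, ...) {
  p <- x@profile
  graphics::plot(p$mid, p$mean_force_pN, type = "l",
                 xlab = "extension (A)", ylab = "force (pN)", ...)
  graphics::arrows(p$mid, p$mean_force_pN - p$sem_pN, p$mid,
                   p$mean_force_pN + p$sem_pN, length = 0.02, angle = 90,
                   code = 3, col = "grey60")
  invisible(x)
})
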