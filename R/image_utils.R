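# Binary-image primitives: 8-connected labeling, Moore boundary tracing,
# Zhang-Suen thinning, separable Gaussian smoothing, Otsu threshold.
# Connectivity is 8-connected throughout, matching the boundary-tracing
# semantics of the quantification procedures.

.n8 <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
             c(0, 1), c(1, -1), c(1, 0), c(1, 1))

#' Label 8-connected components of a binary mask
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (i in which(m)) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    lab[i] <- cur
    frontier <- i
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(.n8))) {
        rr <- r + .n8[k, 1]; cc <- c + .n8[k, 2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        id <- (cc[ok] - 1L) * nr + rr[ok]
        id <- id[m[id] & lab[id] == 0L]
        if (length(id)) {
          lab[id] <- cur
          nxt <- c(nxt, id)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

# Moore-neighbor boundary tracing of one component (Jacob stopping).
# Clockwise neighbor order starting west, with rows increasing downward.
.moore_dirs <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                     c(0, 1), c(1, 1), c(1, 0), c(1, -1))

trace_contour <- function(inmask) {
  nr <- nrow(inmask); nc <- ncol(inmask)
  fg <- function(r, c) r >= 1 && c >= 1 && r <= nr && c <= nc && inmask[r, c]
  px <- which(inmask, arr.ind = TRUE)
  ord <- order(px[, 1], px[, 2])
  s <- as.integer(px[ord[1], ])           # uppermost-leftmost pixel
  pts <- list(s)
  p <- s
  bdir <- 1L                              # backtrack direction: west
  second <- NULL
  max_iter <- 4L * nrow(px) + 8L
  for (iter in seq_len(max_iter)) {
    moved <- FALSE
    for (k in 0:7) {
      di <- ((bdir - 1L + k) %% 8L) + 1L
      q <- p + .moore_dirs[di, ]
      if (fg(q[1], q[2])) {
        prev_di <- ((di - 2L) %% 8L) + 1L
        b <- p + .moore_dirs[prev_di, ]   # last background scanned
        prev <- p
        p <- q
        dd <- b - q                       # next scan starts back at b
        bdir <- which(.moore_dirs[, 1] == dd[1] & .moore_dirs[, 2] == dd[2])
        moved <- TRUE
        break
      }
    }
    if (!moved) break                     # isolated pixel
    if (is.null(second)) {
      second <- p
    } else if (prev[1] == s[1] && prev[2] == s[2] &&
               p[1] == second[1] && p[2] == second[2]) {
      break                               # initial transition repeated
    }
    pts[[length(pts) + 1L]] <- p
  }
  contour <- do.call(rbind, pts)
  dimnames(contour) <- list(NULL, c("row", "col"))
  contour
}

# Zhang-Suen thinning; returns a logical skeleton mask.
skeletonize <- function(mask) {
  m <- (mask > 0) * 1L
  shift <- function(x, dr, dc) {
    nr <- nrow(x); nc <- ncol(x)
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift(m, 1, 0);  p3 <- shift(m, 1, -1)
      p4 <- shift(m, 0, -1); p5 <- shift(m, -1, -1)
      p6 <- shift(m, -1, 0); p7 <- shift(m, -1, 1)
      p8 <- shift(m, 0, 1);  p9 <- shift(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
      if (step == 1) {
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6) == 0 & (p4 * p6 * p8) == 0
      } else {
        cond <- m == 1L & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8) == 0 & (p2 * p6 * p8) == 0
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m > 0
}

# Separable Gaussian smoothing with zero padding outside the image.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_dim1 <- function(x) {
    pad <- matrix(0, half, ncol(x))
    xp <- rbind(pad, x, pad)
    f <- apply(xp, 2, function(col)
      as.numeric(stats::filter(col, k, sides = 2)))
    f[(half + 1):(half + nrow(x)), , drop = FALSE]
  }
  t(smooth_dim1(t(smooth_dim1(m * 1))))
}

# Otsu threshold on a numeric image (256-bin histogram).
otsu_threshold <- function(img) {
  rng <- range(img, finite = TRUE)
  if (diff(rng) == 0) return(rng[1])
  h <- hist(as.numeric(img), breaks = seq(rng[1], rng[2], length.out = 257),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  best <- -Inf; thr <- mids[1]
  cw <- cumsum(w); cm <- cumsum(w * mids); mt <- cm[length(cm)]
  for (i in seq_along(mids)[-length(mids)]) {
    w0 <- cw[i]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    m0 <- cm[i] / w0; m1 <- (mt - cm[i]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; thr <- mids[i] }
  }
  thr
}
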