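# Morphological thinning and skeleton decomposition for binary fiber masks.
# Written in-package: the environment provides no R image-processing library.

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen thinning; returns a 1-pixel-wide skeleton of `mask`
skeletonize_mask <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours P2..P9 clockwise from north
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1) {
        cond <- (!(p2 & p4 & p6)) & (!(p4 & p6 & p8))
      } else {
        cond <- (!(p2 & p4 & p8)) & (!(p2 & p6 & p8))
      }
      del <- m & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# label 8-connected components of a logical matrix; returns an integer matrix
label_components_2d <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  npr <- nr + 2
  offs <- as.integer(c(-1, 1, -npr, npr, -npr - 1, -npr + 1, npr - 1, npr + 1))
  labels <- integer(length(pad))
  todo <- pad
  lab <- 0L
  seeds <- which(todo)
  for (s in seeds) {
    if (!todo[s]) next
    lab <- lab + 1L
    frontier <- s
    todo[s] <- FALSE
    labels[s] <- lab
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, "+")))
      nb <- nb[todo[nb]]
      labels[nb] <- lab
      todo[nb] <- FALSE
      frontier <- nb
    }
  }
  matrix(labels, npr, nc + 2)[2:(nr + 1), 2:(nc + 1)]
}

# Decompose a skeleton into branch segments: remove branch points (>= 3
# neighbours), label the remaining 8-connected runs, and measure each run's
# geodesic length in pixels. Orthogonal steps count 1, diagonal steps
# sqrt(2); diagonals that merely cut a corner already covered by two
# orthogonal steps are skipped; +1 pixel accounts for pixel extent, so a
# straight N-pixel run measures N.
skeleton_segments <- function(skel) {
  p2 <- shift_mat(skel, 1, 0);  p3 <- shift_mat(skel, 1, -1)
  p4 <- shift_mat(skel, 0, -1); p5 <- shift_mat(skel, -1, -1)
  p6 <- shift_mat(skel, -1, 0); p7 <- shift_mat(skel, -1, 1)
  p8 <- shift_mat(skel, 0, 1);  p9 <- shift_mat(skel, 1, 1)
  nb <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  body <- skel & nb < 3
  labs <- label_components_2d(body)
  n_seg <- max(labs)
  if (n_seg == 0) return(numeric(0))
  seg_len <- function(lab_mask) {
    east <- lab_mask & shift_mat(lab_mask, 0, -1)
    south <- lab_mask & shift_mat(lab_mask, -1, 0)
    se <- lab_mask & shift_mat(lab_mask, -1, -1)
    sw <- lab_mask & shift_mat(lab_mask, -1, 1)
    # corner-cutting diagonals: skip when an orthogonal 2-step path exists
    se_ok <- se & !(shift_mat(lab_mask, 0, -1) | shift_mat(lab_mask, -1, 0))
    sw_ok <- sw & !(shift_mat(lab_mask, 0, 1) | shift_mat(lab_mask, -1, 0))
    sum(east) + sum(south) + sqrt(2) * (sum(se_ok) + sum(sw_ok)) + 1
  }
  vapply(seq_len(n_seg), function(k) seg_len(labs == k), numeric(1))
}
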