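# 3D binary-image primitives (connected components, hole filling).
# Written in-package: the environment provides no R image-processing library.

# neighbour offsets in a padded linear index space
neighbor_offsets_3d <- function(dims_padded, connectivity = 26) {
  n1 <- dims_padded[1]; n12 <- dims_padded[1] * dims_padded[2]
  if (connectivity == 6) {
    as.integer(c(-1, 1, -n1, n1, -n12, n12))
  } else {
    d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
    as.integer(d$dx + d$dy * n1 + d$dz * n12)
  }
}

pad_3d <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d + 2)
  out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  out
}

unpad_3d <- function(padded) {
  d <- dim(padded) - 2
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

# label connected components of a 3D logical array; returns an integer array
label_components_3d <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3)
  pad <- pad_3d(mask)
  offs <- neighbor_offsets_3d(dim(pad), connectivity)
  labels <- integer(length(pad))
  todo <- as.vector(pad)
  lab <- 0L
  for (s in which(todo)) {
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
  unpad_3d(array(labels, dim(pad)))
}

# keep only components with at least `min_voxels` voxels
prune_small_components <- function(mask, min_voxels, connectivity = 26) {
  if (!any(mask)) return(mask)
  labs <- label_components_3d(mask, connectivity)
  counts <- tabulate(labs[labs > 0])
  keep <- which(counts >= min_voxels)
  array(labs %in% keep, dim(mask))
}

# keep only the largest component
largest_component <- function(mask, connectivity = 26) {
  labs <- label_components_3d(mask, connectivity)
  counts <- tabulate(labs[labs > 0])
  if (!length(counts)) return(mask)
  array(labs == which.max(counts), dim(mask))
}

# fill interior cavities: background voxels not 6-connected to the border
fill_holes_3d <- function(mask) {
  pad <- pad_3d(mask)
  bg <- !pad
  offs <- neighbor_offsets_3d(dim(pad), 6)
  d <- dim(pad)
  reached <- array(FALSE, d)
  # seed with all border voxels that are background
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  frontier <- which(border & bg)
  reached[frontier] <- TRUE
  todo <- as.vector(bg & !reached)
  # offsets applied at the padded border can wrap in linear index space,
  # but any wrapped index lands on another padded-border voxel (already
  # seeded), so no interior voxel is mislabelled
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, offs, "+")))
    nb <- nb[nb >= 1 & nb <= length(pad)]
    nb <- nb[todo[nb]]
    reached[nb] <- TRUE
    todo[nb] <- FALSE
    frontier <- nb
  }
  unpad_3d(pad | (bg & !reached))
}

# deterministic Fibonacci-sphere directions (unit vectors, n x 3)
fibonacci_directions <- function(n = 500) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
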