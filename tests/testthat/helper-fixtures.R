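# Shared fixture builders. All fixtures are generated in code; the paper's
# printed pixel areas are reproduced as connected row-major blocks.

# connected mask with exactly n_px set pixels (rows filled in order)
make_block_mask <- function(n_px, shape = c(200, 200)) {
  stopifnot(n_px <= prod(shape))
  mt <- matrix(FALSE, shape[2], shape[1]) # transposed: column-major fill
  if (n_px > 0) mt[seq_len(n_px)] <- TRUE # = row-major in the final mask
  t(mt)
}

# random simple star-shaped polygon around (0.5, 0.5), normalized coords
random_polygon <- function(n_min = 4, n_max = 10, r_max = 0.35) {
  n <- sample(n_min:n_max, 1)
  ang <- sort(runif(n, 0, 2 * pi))
  rad <- runif(n, 0.08, r_max)
  cbind(x = 0.5 + rad * cos(ang), y = 0.5 + rad * sin(ang))
}

random_annotations <- function(n, conf = NULL) {
  annotation_tbl(
    class = sample(c("BAC", "AS"), n, replace = TRUE),
    vertices = replicate(n, random_polygon(), simplify = FALSE),
    confidence = if (is.null(conf)) round(runif(n), 3) else conf
  )
}

# small synthetic plate used across segmentation tests
small_plate <- function(noise_sd = 0, seed = 1, size = 512,
                        colony_r = 65, halo_r = 90) {
  generate_plate(synth_config(
    image_size_px = size,
    colonies = colony_spec((size - 1) / 2, (size - 1) / 2, colony_r, halo_r),
    noise_sd = noise_sd, seed = seed
  ))
}

# exhaustive max-cardinality matching oracle over scenes with few objects:
# the largest one-to-one pred/truth assignment using only pairs at
# IoU >= threshold
brute_force_tp <- function(preds, truths, threshold) {
  np <- length(preds); nt <- length(truths)
  if (!np || !nt) return(0L)
  iou <- matrix(0, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    iou[i, j] <- suppressWarnings(mask_iou(preds[[i]], truths[[j]]))
  }
  best <- 0L
  assign_next <- function(i, used, count) {
    if (i > np) { best <<- max(best, count); return(invisible()) }
    assign_next(i + 1L, used, count)           # leave pred i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && iou[i, j] >= threshold) {
        used[j] <- TRUE
        assign_next(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, nt), 0L)
  best
}

# scene of well-separated disks on a small grid; returns masks
disk_scene <- function(centers, radii, shape = c(120, 120)) {
  Map(function(cen, r) rasterize_disk(cen, r, shape), centers, radii)
}
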