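# Independent reference implementations used to cross-check the package:
# a voxel-wise fuzzy c-means (no histogram shortcut) and a plain R
# flood-fill component labeller.  Both are deliberately written without
# reusing any package internals beyond the same initialisation convention.

# Voxel-wise fuzzy c-means on raw intensities; centroids initialised at
# evenly spaced positions across the intensity range, iterated until the
# maximum centroid change is below tol.
oracle_fcm <- function(x, k = 3L, m = 2, tol = 1e-5, max_iter = 100L) {
  x <- as.numeric(x)
  rng <- range(x)
  cent <- rng[1] + (rng[2] - rng[1]) * (2 * seq_len(k) - 1) / (2 * k)
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- pmax(outer(x, cent, function(a, b) (a - b)^2), 1e-300)
    e <- d2^(-1 / (m - 1))
    u <- e / rowSums(e)
    um <- u^m
    newc <- colSums(um * x) / colSums(um)
    delta <- max(abs(newc - cent))
    cent <- newc
    if (delta < tol) break
  }
  ord <- order(cent)
  list(centroids = cent[ord], membership = u[, ord, drop = FALSE],
       labels = max.col(u[, ord, drop = FALSE], ties.method = "first"))
}

# Recursive flood fill over a 3-D logical array with 6/18/26 adjacency.
oracle_flood_fill <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  offs <- offs[man > 0 & man <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  labels <- array(0L, d)
  cur <- 0L
  for (start in which(mask)) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      z <- (v - 1L) %/% (d[1] * d[2]) + 1L
      rem <- (v - 1L) %% (d[1] * d[2])
      y <- rem %/% d[1] + 1L
      x <- rem %% d[1] + 1L
      for (o in seq_len(nrow(offs))) {
        nx <- x + offs[o, 1]; ny <- y + offs[o, 2]; nz <- z + offs[o, 3]
        if (nx < 1 || nx > d[1] || ny < 1 || ny > d[2] || nz < 1 ||
            nz > d[3]) next
        w <- nx + d[1] * (ny - 1L) + d[1] * d[2] * (nz - 1L)
        if (mask[w] && labels[w] == 0L) {
          labels[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  labels
}

# Multiset of component sizes under a labelling (ignores label identity).
component_sizes <- function(labels) {
  sort(as.vector(table(labels[labels > 0])))
}

# A small volume whose bright blob is centred; used for separable-toy
# classifier tests.  Center brightness controls the label.
toy_patch <- function(bright, seed) {
  withr::with_seed(seed, {
    p <- array(stats::rnorm(32^3, 0, 0.1), c(32, 32, 32))
    if (bright) {
      idx <- 13:20
      p[idx, idx, idx] <- p[idx, idx, idx] + 2
    }
    p
  })
}

toy_patch_set <- function(n_pos, n_neg, seed) {
  n <- n_pos + n_neg
  vox <- matrix(0, 32^3, n)
  lab <- integer(n)
  for (i in seq_len(n)) {
    lab[i] <- as.integer(i <= n_pos)
    vox[, i] <- as.vector(toy_patch(lab[i] == 1L, seed + i))
  }
  new("PatchSet", voxels = vox, labels = lab,
      meta = data.frame(participant_id = sprintf("T%03d", seq_len(n)),
                        provenance = "lesion", x_mm = 0, y_mm = 0, z_mm = 0,
                        stringsAsFactors = FALSE))
}

# In-memory mini cohort shared by patchkit/pipeline tests.
mini_cohort <- function(n = 12, prevalence = 0.5, seed = 5,
                        noise_sd = 0.05) {
  makeCohort(n, prevalence, lesion_mix = c(stenosis = 1),
             noise_sd = noise_sd, seed = seed, out_dir = NULL)
}
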