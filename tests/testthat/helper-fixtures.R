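# Fixture builders and slow, independent brute-force oracles used across
# the suite. Oracles deliberately use plain loops and explicit image
# enumeration so they share no code path with the implementation.

make_atoms <- function(element, x, y, z, name = element,
                       residue = "UNK", molecule_id = seq_along(element)) {
  data.frame(atom_id = seq_along(element), element = element, name = name,
             residue = residue, resid = 1L, molecule_id = molecule_id,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

big_box <- function(a = 100) unit_cell(a, a, a)

# random periodic frame of small rigid "molecules" (N-H donor, C=O
# acceptor, one carbon), uniformly placed in a triclinic cell
random_frame <- function(n_mol = 40, seed = 1,
                         cell = unit_cell(22, 19, 25, 80, 95, 104)) {
  set.seed(seed)
  rows <- list()
  for (m in seq_len(n_mol)) {
    cen <- frac_to_cart(cell, stats::runif(3))
    local <- rbind(N = c(0, 0, 0),
                   H = c(1.0, 0, 0),
                   C = c(-0.8, 1.1, 0),
                   O = c(-0.9, 1.2, 1.2),
                   C2 = c(0.3, -1.2, 0.5))
    # random rigid rotation
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)
    ), 3, 3, byrow = TRUE)
    p <- sweep(local %*% t(R), 2, cen, "+")
    rows[[m]] <- make_atoms(c("N", "H", "C", "O", "C"), p[, 1], p[, 2], p[, 3],
                            name = rownames(local), molecule_id = rep(m, 5))
  }
  at <- do.call(rbind, rows)
  at$atom_id <- seq_len(nrow(at))
  crystal_structure(at, cell, assign_molecules = FALSE)
}

# exact minimum-image distance by enumerating a 5x5x5 block of images
brute_image_block <- function(cell) {
  g <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  g %*% t(cell$m)
}

brute_min_dist <- function(cell, p, q, block = brute_image_block(cell)) {
  d2 <- rowSums(sweep(block, 2, q - p, "+")^2)
  sqrt(min(d2))
}

# independent H-bond oracle: nearest-heavy hydrogen attachment, then all
# donor/acceptor pairs with explicit image enumeration
brute_hbonds <- function(structure, criteria = hbond_criteria()) {
  at <- structure$atoms
  pos <- as.matrix(at[, c("x", "y", "z")])
  el <- toupper(at$element)
  n <- nrow(at)
  block <- brute_image_block(structure$cell)
  nearest_img <- function(p, q) {
    # image of q nearest p
    d2 <- rowSums(sweep(block, 2, q - p, "+")^2)
    k <- which.min(d2)
    list(pos = q + block[k, ], dist = sqrt(d2[k]))
  }
  owner <- rep(NA_integer_, n)
  for (h in which(el == "H")) {
    best <- 1.5; who <- NA_integer_
    for (x in which(el != "H")) {
      d <- brute_min_dist(structure$cell, pos[h, ], pos[x, ], block)
      if (d < best) { best <- d; who <- x }
    }
    owner[h] <- who
  }
  res <- list()
  donors <- which(el %in% criteria$donor_elements)
  acceptors <- which(el %in% criteria$acceptor_elements)
  for (d in donors) {
    hs <- which(owner == d)
    if (!length(hs)) next
    for (a in acceptors) {
      if (a == d) next
      if (at$molecule_id[a] == at$molecule_id[d]) next
      aa <- nearest_img(pos[d, ], pos[a, ])
      if (aa$dist > criteria$donor_acceptor_max) next
      for (h in hs) {
        hh <- nearest_img(pos[d, ], pos[h, ])
        v1 <- pos[d, ] - hh$pos
        v2 <- aa$pos - hh$pos
        ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= criteria$dha_angle_min) {
          res[[length(res) + 1L]] <- c(d, h, a, aa$dist, ang)
        }
      }
    }
  }
  if (!length(res)) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), da_distance = numeric(),
                      dha_angle = numeric()))
  }
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("donor", "hydrogen", "acceptor", "da_distance", "dha_angle")
  out[order(out$donor, out$acceptor), ]
}

# independent heavy-atom contact oracle
brute_contacts <- function(structure, criteria = contact_criteria()) {
  at <- structure$atoms
  pos <- as.matrix(at[, c("x", "y", "z")])
  el <- toupper(at$element)
  heavy <- which(el != "H")
  block <- brute_image_block(structure$cell)
  res <- list()
  for (ii in seq_along(heavy)) {
    for (jj in seq_len(ii - 1L)) {
      i <- heavy[ii]; j <- heavy[jj]
      if (at$molecule_id[i] == at$molecule_id[j]) next
      lim <- if (el[i] == "C" && el[j] == "C") criteria$cc_cutoff else criteria$other_cutoff
      d <- brute_min_dist(structure$cell, pos[i, ], pos[j, ], block)
      if (d <= lim) res[[length(res) + 1L]] <- c(min(i, j), max(i, j), d)
    }
  }
  if (!length(res)) return(data.frame(i = integer(), j = integer(), dist = numeric()))
  out <- as.data.frame(do.call(rbind, res))
  names(out) <- c("i", "j", "dist")
  out[order(out$i, out$j), ]
}

# canonical sorted key for comparing bond sets
hb_key <- function(hb) {
  if (!nrow(hb)) return(character(0))
  sort(paste(hb$donor, hb$hydrogen, hb$acceptor, sep = "-"))
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)
  ), 3, 3, byrow = TRUE)
}

# rigidly transform a (padded-cell) structure
transform_structure <- function(structure, R = diag(3), t = c(0, 0, 0)) {
  p <- as.matrix(structure$atoms[, c("x", "y", "z")]) %*% t(R)
  p <- sweep(p, 2, t, "+")
  structure$atoms[, c("x", "y", "z")] <- p
  structure$cell <- unit_cell(200, 200, 200)
  structure
}
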