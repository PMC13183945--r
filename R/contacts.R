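#' Heavy-atom contact criteria
#'
#' A contact is a pair of non-hydrogen atoms within 5.4 A for
#' carbon-carbon pairs or 4.6 A for any other element pair (0.54 / 0.46 nm).
#'
#' @param cc_cutoff Angstrom, carbon-carbon.
#' @param other_cutoff Angstrom, all other pairs.
#' @return list of class `contact_criteria`.
#' @export
contact_criteria <- function(cc_cutoff = 5.4, other_cutoff = 4.6) {
  stopifnot(cc_cutoff > 0, other_cutoff > 0)
  structure(list(cc_cutoff = cc_cutoff, other_cutoff = other_cutoff),
            class = "contact_criteria")
}

# intermolecular contacts in one frame: data.frame(i, j, dist)
frame_contacts <- function(structure, criteria = contact_criteria(),
                           frame = NULL) {
  if (!is.null(frame)) structure <- `coords<-`(structure, frame)
  at <- structure$atoms
  heavy <- which(toupper(at$element) != "H")
  pr <- neighbor_pairs(structure$cell, coords(structure)[heavy, , drop = FALSE],
                       max(criteria$cc_cutoff, criteria$other_cutoff))
  if (!nrow(pr)) return(pr)
  pr$i <- heavy[pr$i]; pr$j <- heavy[pr$j]
  is_cc <- toupper(at$element[pr$i]) == "C" & toupper(at$element[pr$j]) == "C"
  lim <- ifelse(is_cc, criteria$cc_cutoff, criteria$other_cutoff)
  pr <- pr[pr$dist <= lim & at$molecule_id[pr$i] != at$molecule_id[pr$j], , drop = FALSE]
  rownames(pr) <- NULL
  pr
}

#' Group-group contact map over trajectory frames
#'
#' For every pair of chemical groups, the mean number of intermolecular
#' atom-pair contacts per frame and the contact probability (fraction of
#' frames with at least one contact), restricted to a frame window.
#'
#' @param frames list of Nx3 coordinate matrices, or a [trajectory()]
#'   (whose frames/cells are then used).
#' @param structure an `xtal` giving atom metadata and (fallback) cell.
#' @param groups factor from [assign_groups()].
#' @param criteria a [contact_criteria()].
#' @param window `c(first, last)` frame indices (1-based, inclusive), or
#'   `NULL` for the default final half of the frames (the equilibrated
#'   window of an MD run).
#' @return object of class `contact_map`: list with symmetric matrices
#'   `mean_count` and `probability` over group pairs, plus `n_frames`,
#'   `n_cells`, `window`.
#' @export
contact_map <- function(frames, structure, groups,
                        criteria = contact_criteria(), window = NULL) {
  cells <- NULL
  if (inherits(frames, "trajectory")) {
    structure <- frames$topology
    cells <- frames$cells
    frames <- frames$frames
  }
  stopifnot(is_xtal(structure), length(frames) >= 1L)
  if (length(groups) != nrow(structure$atoms)) {
    stop("groups must have one label per atom")
  }
  nf <- length(frames)
  if (is.null(window)) window <- c(max(1L, floor(nf / 2) + 1L), nf)
  if (window[1] < 1L || window[2] > nf || window[1] > window[2]) {
    stop("frame window [", window[1], ", ", window[2],
         "] outside trajectory (1..", nf, ")")
  }
  idx <- seq(window[1], window[2])
  lev <- levels(groups)
  ng <- length(lev)
  count_sum <- matrix(0, ng, ng, dimnames = list(lev, lev))
  any_frames <- matrix(0, ng, ng, dimnames = list(lev, lev))
  gi <- as.integer(groups)
  for (k in idx) {
    s <- structure
    if (!is.null(cells)) s$cell <- cells[[k]]
    ct <- frame_contacts(s, criteria, frame = frames[[k]])
    fc <- matrix(0, ng, ng)
    if (nrow(ct)) {
      g1 <- gi[ct$i]; g2 <- gi[ct$j]
      for (r in seq_along(g1)) {
        fc[g1[r], g2[r]] <- fc[g1[r], g2[r]] + 1
        if (g1[r] != g2[r]) fc[g2[r], g1[r]] <- fc[g2[r], g1[r]] + 1
      }
    }
    count_sum <- count_sum + fc
    any_frames <- any_frames + (fc > 0)
  }
  structure(list(
    mean_count = count_sum / length(idx),
    probability = any_frames / length(idx),
    n_frames = length(idx),
    n_cells = structure$n_cells,
    window = window
  ), class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact map over", x$n_frames, "frame(s), n_cells =", x$n_cells, "\n")
  print(round(x$probability, 3))
  invisible(x)
}

#' Normalize a count per crystal unit
#'
#' @param count numeric count(s) measured over a supercell.
#' @param n_cells number of unit cells in the supercell (`>= 1`).
#' @return `count / n_cells`.
#' @examples
#' per_unit(432, 216)  # 2
#' @export
per_unit <- function(count, n_cells) {
  if (length(n_cells) != 1L || is.na(n_cells) || n_cells < 1) {
    stop("n_cells must be a single integer >= 1")
  }
  count / n_cells
}
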