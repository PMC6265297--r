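#' Backbone structures and secondary-structure classification
#'
#' This module classifies per-residue secondary structure (alpha, 3-10,
#' pi, turn, coil) from backbone hydrogen-bond patterns across structure
#' frames, with explicit handling of amide-to-ester (alpha-hydroxy acid)
#' substitutions: an esterified residue has its backbone N-H replaced by
#' an ester oxygen and therefore cannot donate a main-chain hydrogen
#' bond, deleting exactly one H-bond from the helix.
#'
#' A `bb_structure` stores, per frame, the backbone atoms N, CA, C, O
#' (and optionally H) for each residue, plus residue/chain identifiers
#' and the set of ester sites.
#'
#' @name bb_structure
NULL

new_bb_structure <- function(frames, resno, chain, resid = NULL,
                             ester_sites = integer(), usable = NULL) {
  if (is.null(usable)) usable <- rep(TRUE, length(resno))
  structure(list(frames = frames, resno = resno, chain = chain,
                 resid = if (is.null(resid)) rep("ALA", length(resno)) else resid,
                 ester_sites = ester_sites, usable = usable),
            class = "bb_structure")
}

#' Number of frames / residues of a structure
#' @param structure a `bb_structure`.
#' @return integer count.
#' @export
n_frames <- function(structure) length(structure$frames)

#' @rdname n_frames
#' @export
n_residues <- function(structure) length(structure$resno)

#' Read a (multi-model) PDB file into a backbone structure
#'
#' MODEL records become frames; every frame must share the residue
#' topology of the first.  Residues missing any of N, CA, C, O are
#' flagged unusable (excluded as donors and acceptors) with a warning.
#' Parsing is delegated to `bio3d::read.pdb`.
#'
#' @param path path to a PDB file.
#' @return a `bb_structure`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  if (!nrow(at)) stop("no ATOM records in ", path)
  key <- paste(at$chain, at$resno)
  res_keys <- unique(key)
  resno <- at$resno[match(res_keys, key)]
  chain <- at$chain[match(res_keys, key)]
  resid <- at$resid[match(res_keys, key)]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nfr <- nrow(xyz)
  usable <- rep(TRUE, length(res_keys))
  frames <- vector("list", nfr)
  atom_row <- function(name) {
    idx <- rep(NA_integer_, length(res_keys))
    sel <- which(at$elety == name)
    idx[match(key[sel], res_keys)] <- sel
    idx
  }
  rows <- lapply(c(N = "N", CA = "CA", C = "C", O = "O", H = "H"), atom_row)
  missing_core <- is.na(rows$N) | is.na(rows$CA) | is.na(rows$C) | is.na(rows$O)
  if (any(missing_core)) {
    warning("residue(s) missing backbone atoms excluded: ",
            paste(resno[missing_core], collapse = ", "))
    usable[missing_core] <- FALSE
  }
  get_coords <- function(fr, idx) {
    out <- matrix(NA_real_, length(idx), 3L)
    ok <- !is.na(idx)
    cols <- as.vector(t(outer(idx[ok], c(-2L, -1L, 0L), function(i, o) 3L * i + o)))
    out[ok, ] <- matrix(xyz[fr, cols], ncol = 3L, byrow = TRUE)
    out
  }
  for (fr in seq_len(nfr)) {
    frames[[fr]] <- list(N = get_coords(fr, rows$N), CA = get_coords(fr, rows$CA),
                         C = get_coords(fr, rows$C), O = get_coords(fr, rows$O),
                         H = get_coords(fr, rows$H))
  }
  new_bb_structure(frames, resno, chain, resid, usable = usable)
}

#' Write a backbone structure as a multi-model PDB file
#'
#' @param structure a `bb_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  for (fr in seq_len(n_frames(structure))) {
    writeLines(sprintf("MODEL     %4d", fr), con)
    f <- structure$frames[[fr]]
    for (i in seq_len(n_residues(structure))) {
      for (nm in c("N", "CA", "C", "O", "H")) {
        xyz <- f[[nm]][i, ]
        if (any(is.na(xyz))) next
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
          serial %% 100000L, ifelse(nchar(nm) < 4, paste0(" ", nm), nm),
          structure$resid[i], structure$chain[i], structure$resno[i],
          xyz[1], xyz[2], xyz[3], substr(nm, 1, 1)), con)
      }
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Place amide hydrogens by the standard reconstruction
#'
#' For each residue i >= 2 lacking an H record, places H at 1.01 A from N
#' along the bisector direction `(N - C_prev)/|.| + (N - O_prev)/|.|`
#' (normalized), i.e. opposite the carbonyl of the preceding peptide
#' group.  No hydrogen is placed for prolines, ester sites (which have no
#' N-H), chain-initial residues, or residues flagged unusable.  Existing
#' H coordinates are retained.
#'
#' @param structure a `bb_structure`.
#' @return the structure with H coordinates filled in.
#' @export
place_amide_hydrogens <- function(structure) {
  nres <- n_residues(structure)
  for (fr in seq_len(n_frames(structure))) {
    f <- structure$frames[[fr]]
    if (is.null(f$H)) f$H <- matrix(NA_real_, nres, 3L)
    for (i in 2:nres) {
      if (!all(is.na(f$H[i, ]))) next  # keep provided H
      if (!structure$usable[i] || !structure$usable[i - 1L]) next
      if (structure$resno[i] %in% structure$ester_sites) next
      if (structure$resid[i] == "PRO") next
      if (structure$chain[i] != structure$chain[i - 1L]) next
      v1 <- f$N[i, ] - f$C[i - 1L, ]
      v2 <- f$N[i, ] - f$O[i - 1L, ]
      u <- v1 / sqrt(sum(v1^2)) + v2 / sqrt(sum(v2^2))
      u <- u / sqrt(sum(u^2))
      f$H[i, ] <- f$N[i, ] + 1.01 * u
    }
    structure$frames[[fr]] <- f
  }
  structure
}

#' Electrostatic backbone hydrogen-bond energy
#'
#' The classic DSSP-style point-charge criterion between a donor N-H and
#' an acceptor C=O:
#'
#' `E = 27.888 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol
#'
#' with distances in Angstrom; a bond is recorded when `E < -0.5`
#' kcal/mol.  Donors without a hydrogen (ester sites, prolines, chain
#' starts) have no energy: `NA` is returned, never a numeric zero.
#'
#' @param donor list with `N` and `H` coordinates (length-3 vectors).
#' @param acceptor list with `C` and `O` coordinates.
#' @return energy in kcal/mol, or `NA_real_` if the donor cannot donate.
#' @export
hbond_energy <- function(donor, acceptor) {
  if (is.null(donor$H) || any(is.na(donor$H))) return(NA_real_)
  d <- function(a, b) sqrt(sum((a - b)^2))
  27.888 * (1 / d(acceptor$O, donor$N) + 1 / d(acceptor$C, donor$H) -
            1 / d(acceptor$O, donor$H) - 1 / d(acceptor$C, donor$N))
}

#' Backbone hydrogen bonds of one frame
#'
#' Enumerates all donor (N-H of residue j) / acceptor (C=O of residue i)
#' pairs with |j - i| >= 2 and records those with DSSP energy below the
#' cutoff.
#'
#' @param structure a `bb_structure` with hydrogens placed.
#' @param frame frame index.
#' @param cutoff bond-energy cutoff, kcal/mol.
#' @return data.frame (donor, acceptor, energy, k) where `donor` and
#'   `acceptor` are residue indices (1-based positions in the structure)
#'   and `k = donor - acceptor` is the sequence separation.
#' @export
backbone_hbonds <- function(structure, frame = 1L, cutoff = -0.5) {
  f <- structure$frames[[frame]]
  nres <- n_residues(structure)
  out <- list()
  for (j in seq_len(nres)) {       # donor
    if (!structure$usable[j]) next
    if (structure$resno[j] %in% structure$ester_sites) next
    if (is.null(f$H) || any(is.na(f$H[j, ]))) next
    donor <- list(N = f$N[j, ], H = f$H[j, ])
    for (i in seq_len(nres)) {     # acceptor
      if (abs(j - i) < 2L) next
      if (!structure$usable[i]) next
      if (any(is.na(f$O[i, ])) || any(is.na(f$C[i, ]))) next
      e <- hbond_energy(donor, list(C = f$C[i, ], O = f$O[i, ]))
      if (!is.na(e) && e < cutoff)
        out[[length(out) + 1L]] <- data.frame(donor = j, acceptor = i,
                                              energy = e, k = j - i)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(), acceptor = integer(),
                      energy = numeric(), k = integer()))
  do.call(rbind, out)
}

#' Assign per-residue secondary structure from H-bond patterns
#'
#' DSSP-convention minimal-helix rules on the i+k -> i backbone H-bonds
#' (donor at i+k, acceptor at i): two consecutive k-turns (at i-1 and i)
#' start a helix covering residues i..i+k-1; k = 3 gives G (3-10 helix),
#' k = 4 gives H (alpha), k = 5 gives I (pi), with overlap priority
#' H > G > I.  Residues inside an isolated single turn are labeled T;
#' everything else is C (coil).
#'
#' @param structure a `bb_structure` with hydrogens placed.
#' @param frame frame index.
#' @param hbonds optionally, a precomputed bond table from
#'   [backbone_hbonds()].
#' @return character vector of labels in \{"H","G","I","T","C"\}, one per
#'   residue.
#' @export
assign_secondary_structure <- function(structure, frame = 1L,
                                       hbonds = NULL) {
  if (is.null(hbonds)) hbonds <- backbone_hbonds(structure, frame)
  nres <- n_residues(structure)
  labels <- rep("C", nres)
  turn <- function(k) {
    t <- rep(FALSE, nres)
    acc <- hbonds$acceptor[hbonds$k == k]
    t[acc] <- TRUE
    t
  }
  turns <- list(`3` = turn(3L), `4` = turn(4L), `5` = turn(5L))
  # helix assignment in priority order H (k=4) > G (k=3) > I (k=5)
  for (cls in list(c(4L, "H"), c(3L, "G"), c(5L, "I"))) {
    k <- as.integer(cls[1L]); lab <- cls[2L]
    t <- turns[[as.character(k)]]
    for (i in which(t)) {
      if (i > 1L && t[i - 1L]) {
        span <- i:min(i + k - 1L, nres)
        free <- labels[span] %in% c("C", "T")
        labels[span][free] <- lab
      }
    }
  }
  # isolated turns
  for (k in c(3L, 4L, 5L)) {
    t <- turns[[as.character(k)]]
    for (i in which(t)) {
      span <- (i + 1L):min(i + k - 1L, nres)
      labels[span][labels[span] == "C"] <- "T"
    }
  }
  labels
}

#' Introduce an amide-to-ester substitution
#'
#' Adds `site` (a residue number) to the structure's ester sites: the
#' backbone N-H of that residue is replaced by an ester oxygen, so the
#' residue can no longer donate a main-chain hydrogen bond.  Its H
#' coordinates are removed; acceptor capabilities (its own C=O, and every
#' other residue) are untouched.  Idempotent.
#'
#' @param structure a `bb_structure`.
#' @param site residue number (as in `structure$resno`).
#' @return the modified structure.
#' @export
apply_ester <- function(structure, site) {
  idx <- which(structure$resno == site)
  if (!length(idx)) stop("unknown residue: ", site)
  structure$ester_sites <- sort(unique(c(structure$ester_sites, site)))
  for (fr in seq_len(n_frames(structure))) {
    if (!is.null(structure$frames[[fr]]$H))
      structure$frames[[fr]]$H[idx, ] <- NA_real_
  }
  structure
}

#' Per-residue secondary-structure content over frames
#'
#' Fraction of frames in which each residue carries each label; rows sum
#' to 1.
#'
#' @param structure a `bb_structure` with hydrogens placed.
#' @param residue_range optional residue-number range c(lo, hi).
#' @return data.frame (resno, H, G, I, T, C) of per-class fractions.
#' @export
helical_content <- function(structure, residue_range = NULL) {
  nfr <- n_frames(structure)
  if (!nfr) stop("structure has no frames")
  labs <- vapply(seq_len(nfr),
                 function(fr) assign_secondary_structure(structure, fr),
                 character(n_residues(structure)))
  labs <- matrix(labs, nrow = n_residues(structure))
  keep <- seq_len(n_residues(structure))
  if (!is.null(residue_range)) {
    keep <- which(structure$resno >= residue_range[1] &
                  structure$resno <= residue_range[2])
    if (!length(keep)) stop("empty residue range")
  }
  classes <- c("H", "G", "I", "T", "C")
  frac <- t(apply(labs[keep, , drop = FALSE], 1L, function(r)
    vapply(classes, function(cl) mean(r == cl), 0)))
  out <- data.frame(resno = structure$resno[keep], frac)
  names(out) <- c("resno", classes)
  out
}

# Extend a chain by one atom using internal coordinates (NeRF): new atom
# at distance `bond` from atom c, with angle a-b-c ... c-new = `angle`
# (degrees) and dihedral a-b-c-new = `dihedral` (degrees).
nerf_place <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * cos(dih) * sin(ang),
          bond * sin(dih) * sin(ang))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma::cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cbind(bc, pracma::cross(n, bc), n)
  drop(m %*% d2) + c
}

#' Build an ideal poly-alanine-like backbone helix
#'
#' Constructs an n-residue backbone (N, CA, C, O) by internal-coordinate
#' chain extension with standard geometry (N-CA 1.458, CA-C 1.525,
#' C-N 1.329, C=O 1.231 A; angles C-N-CA 121.7, N-CA-C 111.2,
#' CA-C-N 116.2 degrees) at the requested backbone dihedrals.  Canonical
#' fixtures: alpha helix phi = -57, psi = -47; 3-10 helix phi = -49,
#' psi = -26; extended chain phi = psi = 180.
#'
#' @param n_res number of residues (>= 4).
#' @param phi_deg,psi_deg,omega_deg backbone dihedrals, degrees.
#' @param chain chain identifier.
#' @param resno_start first residue number.
#' @return a `bb_structure` with one frame (H not yet placed; use
#'   [place_amide_hydrogens()]).
#' @export
build_ideal_helix <- function(n_res, phi_deg, psi_deg, omega_deg = 180,
                              chain = "A", resno_start = 1L) {
  if (n_res < 4L) stop("n_res must be >= 4")
  bN_CA <- 1.458; bCA_C <- 1.525; bC_N <- 1.329; bC_O <- 1.231
  aC_N_CA <- 121.7; aN_CA_C <- 111.2; aCA_C_N <- 116.2; aCA_C_O <- 120.8
  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3L)
  # seed residue 1
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(bN_CA, 0, 0)
  ac <- aN_CA_C * pi / 180
  C[1L, ] <- CA[1L, ] + bCA_C * c(-cos(ac), sin(ac), 0)
  for (i in 2:n_res) {
    N[i, ] <- nerf_place(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                         bC_N, aCA_C_N, psi_deg)
    CA[i, ] <- nerf_place(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                          bN_CA, aC_N_CA, omega_deg)
    C[i, ] <- nerf_place(C[i - 1L, ], N[i, ], CA[i, ],
                         bCA_C, aN_CA_C, phi_deg)
  }
  for (i in seq_len(n_res)) {
    if (i < n_res) {
      # O anti to the next amide nitrogen, in the peptide plane
      O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], bC_O, aCA_C_O,
                           psi_deg + 180)
    } else {
      O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], bC_O, aCA_C_O,
                           psi_deg + 180)
    }
  }
  frames <- list(list(N = N, CA = CA, C = C, O = O,
                      H = matrix(NA_real_, n_res, 3L)))
  new_bb_structure(frames, resno = seq.int(resno_start,
                                           length.out = n_res),
                   chain = rep(chain, n_res))
}

#' Shaker / Kv1.2-2.1 chimera S4 residue-number correspondence
#'
#' Offset map between Shaker S4 numbering and the Kv1.2/2.1 chimera
#' construct used for activated-state structures (V363 <-> I291,
#' V369 <-> I297; constant offset -72).
#'
#' @param shaker_resno Shaker residue number(s).
#' @return chimera residue number(s).
#' @export
shaker_to_chimera <- function(shaker_resno) shaker_resno - 72L

#' @rdname shaker_to_chimera
#' @param chimera_resno chimera residue number(s).
#' @export
chimera_to_shaker <- function(chimera_resno) chimera_resno + 72L
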