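# Ionic-strength arithmetic and solvated-box composition utilities.

#' Build an ion species table
#'
#' An ion species table is a tibble with one row per dissolved ionic species
#' and columns `label`, `charge` (units of the elementary charge e, nonzero
#' integer) and `concentration` (mol/L, non-negative). It is the common
#' currency of [ionic_strength()], [ion_counts_for_box()] and the survey
#' annotator.
#'
#' @param label Character vector of species names.
#' @param charge Integer vector of ionic charges in units of e.
#' @param concentration Numeric vector of molar concentrations (mol/L).
#' @return A tibble with columns `label`, `charge`, `concentration`.
#' @examples
#' ion_species(c("Ca2+", "Cl-"), c(2L, -1L), c(0.025, 0.050))
#' @export
ion_species <- function(label, charge, concentration) {
  spc <- tibble(
    label = as.character(label),
    charge = as.integer(charge),
    concentration = as.numeric(concentration)
  )
  validate_species(spc)
  spc
}

validate_species <- function(species) {
  req <- c("label", "charge", "concentration")
  if (!is.data.frame(species) || !all(req %in% names(species))) {
    abort("`species` must be a data frame with columns label, charge, concentration.")
  }
  if (any(species$charge == 0)) abort("Ion charges must be nonzero.")
  if (any(!is.finite(species$concentration)) || any(species$concentration < 0)) {
    abort("Ion concentrations must be finite and >= 0.")
  }
  invisible(species)
}

#' Species table for a named salt
#'
#' Expands a salt from the supported crystallization-buffer vocabulary
#' (NaCl, KCl, CaCl2, MgCl2, MnCl2) into its fully dissociated ion species
#' at the given salt concentration. 2:1 salts contribute the anion at twice
#' the salt concentration.
#'
#' @param salt Salt name (case-insensitive), e.g. `"CaCl2"`.
#' @param concentration Salt concentration in mol/L.
#' @return An ion species table (see [ion_species()]).
#' @examples
#' salt_species("CaCl2", 0.1)
#' @export
salt_species <- function(salt, concentration) {
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      !is.finite(concentration) || concentration < 0) {
    abort("`concentration` must be a single non-negative number (mol/L).")
  }
  key <- toupper(salt)
  tab <- list(
    NACL  = list(cation = "Na+", z = 1L, stoich = 1L),
    KCL   = list(cation = "K+",  z = 1L, stoich = 1L),
    CACL2 = list(cation = "Ca2+", z = 2L, stoich = 2L),
    MGCL2 = list(cation = "Mg2+", z = 2L, stoich = 2L),
    MNCL2 = list(cation = "Mn2+", z = 2L, stoich = 2L)
  )
  if (!key %in% names(tab)) {
    abort(paste0("Unsupported salt '", salt, "'. Supported: NaCl, KCl, CaCl2, MgCl2, MnCl2."))
  }
  s <- tab[[key]]
  ion_species(
    label = c(s$cation, "Cl-"),
    charge = c(s$z, -1L),
    concentration = c(concentration, s$stoich * concentration)
  )
}

#' Molar ionic strength
#'
#' Computes the molar ionic strength I^M = 1/2 * sum_i c_i * Z_i^2 over the
#' dissolved species. For a fully dissociated 2:1 salt such as CaCl2 at salt
#' concentration c this equals 3c.
#'
#' @param species Ion species table (see [ion_species()]). May be empty.
#' @return Ionic strength in mol/L (a single number).
#' @examples
#' ionic_strength(salt_species("CaCl2", 0.025)) # 0.075
#' ionic_strength(salt_species("NaCl", 0.1))    # 0.1
#' @export
ionic_strength <- function(species) {
  validate_species(species)
  if (nrow(species) == 0) return(0)
  0.5 * sum(species$concentration * species$charge^2)
}

#' Integer ion counts realizing a concentration in a cubic box
#'
#' Converts per-species molar concentrations into integer particle counts
#' for a cubic periodic box: cation counts are `round(c * N_A * V)`
#' (round-half-to-even), and the anion count is then set by exact charge
#' balance so the salt stoichiometry is restored after rounding.
#'
#' @param species Ion species table (a single salt: one cation species and
#'   one anion species, e.g. from [salt_species()]).
#' @param box_edge Cubic box edge length in Angstrom.
#' @return A tibble with columns `label`, `charge`, `count`.
#' @examples
#' # 0.025 M CaCl2 in the 93 A box: 12 Ca2+, 24 Cl-
#' ion_counts_for_box(salt_species("CaCl2", 0.025), box_edge = 93)
#' @export
ion_counts_for_box <- function(species, box_edge) {
  validate_species(species)
  if (!is.numeric(box_edge) || length(box_edge) != 1 || box_edge <= 0) {
    abort("`box_edge` must be a single positive number (Angstrom).")
  }
  v_litre <- box_edge^3 * 1e-27
  cations <- species[species$charge > 0, , drop = FALSE]
  anions <- species[species$charge < 0, , drop = FALSE]
  if (nrow(anions) != 1) abort("Expected exactly one anion species.")
  n_cat <- round(cations$concentration * .NA_AVOGADRO * v_litre)
  pos_charge <- sum(cations$charge * n_cat)
  n_an <- pos_charge / abs(anions$charge)
  if (n_an != round(n_an)) {
    abort("Anion charge does not divide the cation charge; cannot restore stoichiometry.")
  }
  tibble(
    label = c(cations$label, anions$label),
    charge = c(cations$charge, anions$charge),
    count = as.integer(c(n_cat, n_an))
  )
}

#' Realized species table for counted ions in a box
#'
#' Inverse of [ion_counts_for_box()]: converts integer counts back to
#' concentrations so the realized ionic strength of a composed box can be
#' checked against its target.
#'
#' @param counts Tibble with columns `label`, `charge`, `count`.
#' @param box_edge Cubic box edge in Angstrom.
#' @return An ion species table.
#' @export
counts_to_species <- function(counts, box_edge) {
  stopifnot(all(c("label", "charge", "count") %in% names(counts)))
  v_litre <- box_edge^3 * 1e-27
  keep <- counts$count > 0
  ion_species(
    label = counts$label[keep],
    charge = counts$charge[keep],
    concentration = counts$count[keep] / (.NA_AVOGADRO * v_litre)
  )
}

#' Adjust ion counts to neutralize a charged solute
#'
#' Given the box ion counts and the net charge of an immersed solute
#' (protein), adjusts counts so the total system charge is exactly zero.
#' The adjustment uses the minimal number of added/removed monovalent
#' counterions, adjusting anions first; if no monovalent species is present,
#' a divalent species is used when the residual charge is even.
#'
#' @param counts Tibble with columns `label`, `charge`, `count`.
#' @param solute_net_charge Net solute charge in units of e (integer).
#' @return Adjusted counts tibble satisfying
#'   `sum(charge * count) + solute_net_charge == 0`.
#' @examples
#' cts <- ion_counts_for_box(salt_species("CaCl2", 0.025), 93)
#' neutralize_counts(cts, solute_net_charge = -10) # drops 10 Cl-
#' @export
neutralize_counts <- function(counts, solute_net_charge) {
  stopifnot(all(c("label", "charge", "count") %in% names(counts)))
  if (any(counts$count < 0)) abort("Counts must be >= 0.")
  q <- as.integer(round(solute_net_charge))
  excess <- sum(counts$charge * counts$count) + q
  if (excess == 0) return(counts)

  adjust_with <- function(counts, idx, excess) {
    z <- counts$charge[idx]
    delta <- -excess / z # particles to add (may be negative = remove)
    new_n <- counts$count[idx] + delta
    if (new_n < 0) return(NULL)
    counts$count[idx] <- as.integer(new_n)
    counts
  }

  mono <- which(abs(counts$charge) == 1)
  # anions first among monovalent candidates
  mono <- mono[order(counts$charge[mono])]
  for (idx in mono) {
    out <- adjust_with(counts, idx, excess)
    if (!is.null(out)) return(out)
  }
  if (excess %% 2 == 0) {
    diva <- which(abs(counts$charge) == 2)
    diva <- diva[order(counts$charge[diva])]
    for (idx in diva) {
      out <- adjust_with(counts, idx, excess)
      if (!is.null(out)) return(out)
    }
  }
  abort(paste0(
    "Cannot neutralize residual charge ", excess,
    " e with the available species charges."
  ))
}

#' Randomly place ions in a periodic box with a spacing constraint
#'
#' Sequential random insertion of ions into a cubic periodic box. Each new
#' ion must lie at least `spacing` (minimum-image) from previously placed
#' ions -- from all of them in the default strict mode, or only from the most
#' recently placed ion when `strict = FALSE` -- and at least
#' `solvent_overlap` from any supplied solvent atom. The anti-clustering
#' spacing defaults to 15 Angstrom.
#'
#' @param counts Tibble with columns `label`, `charge`, `count`.
#' @param box_edge Cubic box edge in Angstrom.
#' @param seed Integer seed; placement is bit-reproducible given the seed.
#' @param spacing Minimum ion-ion distance in Angstrom (default 15).
#' @param solvent Optional matrix or data frame of solvent atom coordinates
#'   (columns x, y, z) to avoid.
#' @param solvent_overlap Minimum ion-solvent distance in Angstrom
#'   (default 2.8).
#' @param strict If `TRUE` (default) the spacing applies to all previously
#'   placed ions; if `FALSE`, only to the last one.
#' @param max_attempts Rejection-sampling attempts per ion before failing.
#' @return A tibble with columns `label`, `charge`, `x`, `y`, `z` (Angstrom).
#' @examples
#' cts <- ion_counts_for_box(salt_species("CaCl2", 0.025), 93)
#' ions <- place_ions(cts, box_edge = 93, seed = 1)
#' nrow(ions) # 36
#' @export
place_ions <- function(counts, box_edge, seed, spacing = 15,
                       solvent = NULL, solvent_overlap = 2.8,
                       strict = TRUE, max_attempts = 10000) {
  stopifnot(all(c("label", "charge", "count") %in% names(counts)))
  n_total <- sum(counts$count)
  labels <- rep(counts$label, counts$count)
  charges <- rep(counts$charge, counts$count)
  if (n_total == 0) {
    return(tibble(label = character(), charge = integer(),
                  x = double(), y = double(), z = double()))
  }
  if (!is.null(solvent)) {
    solvent <- as.matrix(as.data.frame(solvent)[, c("x", "y", "z")])
  }
  pos <- matrix(NA_real_, nrow = n_total, ncol = 3)
  local_seed(seed, {
    for (i in seq_len(n_total)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        p <- runif(3, 0, box_edge)
        ok <- TRUE
        if (i > 1) {
          ref <- if (strict) pos[seq_len(i - 1), , drop = FALSE] else pos[i - 1, , drop = FALSE]
          if (min(min_image_dist(p, ref, box_edge)) < spacing) ok <- FALSE
        }
        if (ok && !is.null(solvent) && nrow(solvent) > 0) {
          if (min(min_image_dist(p, solvent, box_edge)) < solvent_overlap) ok <- FALSE
        }
        if (ok) {
          pos[i, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0("Failed to place ion ", i, " of ", n_total, " after ",
                     max_attempts, " attempts (spacing ", spacing, " A in a ",
                     box_edge, " A box)."))
      }
    }
  })
  tibble(label = labels, charge = charges,
         x = pos[, 1], y = pos[, 2], z = pos[, 3])
}

#' Convert placed ions to a PDB-writable atom table
#'
#' Turns a [place_ions()] result into an atom table of HETATM records
#' (atom name and residue name from the first two characters of the ion
#' label), suitable for [write_structure()].
#'
#' @param ions Tibble from [place_ions()].
#' @return An atom table with `type = "HETATM"`.
#' @export
ions_to_atoms <- function(ions) {
  nm <- toupper(gsub("[^A-Za-z]", "", ions$label))
  tibble(
    type = "HETATM",
    name = substr(nm, 1, 2),
    element = substr(nm, 1, 2),
    resname = substr(nm, 1, 3),
    resno = seq_len(nrow(ions)),
    insert = "", chain = "I", alt = "",
    x = ions$x, y = ions$y, z = ions$z
  )
}

#' Remove waters overlapping a protein
#'
#' Drops every water molecule that has any atom within `cutoff` of any
#' protein heavy (non-hydrogen) atom. Waters are removed as whole molecules.
#'
#' @param protein Atom table of the protein (see [read_structure()]); only
#'   heavy atoms (element != "H") are considered.
#' @param waters Data frame of water atoms with columns `x`, `y`, `z` and an
#'   optional `water` molecule-id column (one molecule per distinct id; if
#'   absent, each row is its own molecule).
#' @param cutoff Removal radius in Angstrom (default 2.8).
#' @param box_edge Optional cubic box edge for minimum-image distances.
#' @return The retained rows of `waters`.
#' @export
trim_waters <- function(protein, waters, cutoff = 2.8, box_edge = NULL) {
  stopifnot(all(c("x", "y", "z") %in% names(waters)))
  heavy <- protein[!is.na(protein$element) & toupper(protein$element) != "H", ,
                   drop = FALSE]
  if (nrow(heavy) == 0) abort("No protein heavy atoms identifiable.")
  if (nrow(waters) == 0) return(waters)
  hxyz <- as.matrix(heavy[, c("x", "y", "z")])
  wid <- if ("water" %in% names(waters)) waters$water else seq_len(nrow(waters))
  wxyz <- as.matrix(waters[, c("x", "y", "z")])
  close <- vapply(seq_len(nrow(wxyz)), function(i) {
    min(min_image_dist(wxyz[i, ], hxyz, box_edge)) < cutoff
  }, logical(1))
  bad <- unique(wid[close])
  waters[!wid %in% bad, , drop = FALSE]
}
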