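# Insertion of enzymatic (divalent/trivalent) and AGE cross-links into an
# assembled fibril.

#' Cross-linking configuration
#'
#' @param ecl_content enzymatic cross-link content in percent of
#'   telopeptide ends carrying a cross-link; 100 corresponds to two
#'   enzymatic cross-links per molecule (one at each end).
#' @param ecl_valence `"divalent"` (one bond joining 2 molecules) or
#'   `"trivalent"` (two bonds from the same telopeptide bead to two
#'   distinct molecules, joining 3).
#' @param n_age AGE cross-links per molecule (any non-negative value; the
#'   sweeps of interest use 0, 0.5, 1, 2, 5, 10, 40).
#' @param capture_radius partner search radius (Angstrom). The default of
#'   twice the bead spacing restricts partners to adjacent molecules of the
#'   lattice.
#' @param seed RNG seed for the random placement.
#' @return an object of class `crosslink_config`.
#' @export
crosslink_config <- function(ecl_content = 0, ecl_valence = c("divalent", "trivalent"),
                             n_age = 0, capture_radius = 28, seed = 1L) {
  ecl_valence <- match.arg(ecl_valence)
  if (!is.finite(ecl_content) || ecl_content < 0 || ecl_content > 100) {
    stop("ecl_content must be in [0, 100] percent")
  }
  if (!is.finite(n_age) || n_age < 0) stop("n_age must be non-negative")
  stopifnot(capture_radius > 0)
  structure(list(ecl_content = ecl_content, ecl_valence = ecl_valence,
                 n_age = n_age, capture_radius = capture_radius,
                 seed = as.integer(seed)),
            class = "crosslink_config")
}

check_stage <- function(fibril, strict, what) {
  if (strict && !isTRUE(attr(fibril, "equilibrated"))) {
    stop(what, " insertion before equilibration is rejected; run the ",
         "minimize/equilibrate stages first (see run_protocol)")
  }
}

# Terminal telopeptide bead (the outermost bead of the helical section) of
# each molecule end. Returns data.frame(molecule, end, bead).
telopeptide_ends <- function(system) {
  helical_like <- system$role %in% c("helical", "telopeptide")
  out <- lapply(sort(unique(system$molecule)), function(m) {
    sel <- which(system$molecule == m & helical_like)
    data.frame(molecule = m, end = c("N", "C"), bead = c(min(sel), max(sel)))
  })
  do.call(rbind, out)
}

#' Insert enzymatic cross-links
#'
#' A fraction `ecl_content` percent of all telopeptide ends is selected at
#' random; each selected end gains exactly one cross-link, anchored at its
#' terminal telopeptide bead and attached to the nearest helical bead of
#' the nearest distinct molecule within the capture radius (for trivalent
#' cross-links, additionally to the second-nearest molecule). Ends without
#' a partner in range are skipped and counted in the shortfall report.
#'
#' @param fibril a `fibril` object.
#' @param config a [crosslink_config()].
#' @param strict enforce the pipeline ordering (equilibration before
#'   insertion); used by [run_protocol()].
#' @return the fibril with ECL bonds added; `attr(, "ecl_shortfall")`
#'   reports skipped ends.
#' @export
insert_ecl <- function(fibril, config, strict = FALSE) {
  check_stage(fibril, strict, "enzymatic cross-link")
  stopifnot(inherits(config, "crosslink_config"))
  if (config$ecl_content == 0) {
    attr(fibril, "ecl_shortfall") <- 0L
    return(fibril)
  }
  set.seed(config$seed)
  sys <- fibril$system
  ends <- telopeptide_ends(sys)
  n_sel <- round(config$ecl_content / 100 * nrow(ends))
  sel <- ends[sample.int(nrow(ends), n_sel), , drop = FALSE]
  species <- if (config$ecl_valence == "divalent") "ecl_divalent" else "ecl_trivalent"
  targets <- which(sys$role == "helical")
  existing <- paste(pmin(fibril$topology$bonds$i, fibril$topology$bonds$j),
                    pmax(fibril$topology$bonds$i, fibril$topology$bonds$j))
  new_i <- integer(0); new_j <- integer(0)
  shortfall <- 0L
  for (q in seq_len(nrow(sel))) {
    e <- sel$bead[q]
    cand <- targets[sys$molecule[targets] != sel$molecule[q]]
    d2 <- (sys$pos[cand, 1] - sys$pos[e, 1])^2 +
          (sys$pos[cand, 2] - sys$pos[e, 2])^2 +
          (sys$pos[cand, 3] - sys$pos[e, 3])^2
    ok <- d2 <= config$capture_radius^2
    if (!any(ok)) { shortfall <- shortfall + 1L; next }
    cand <- cand[ok]; d2 <- d2[ok]
    ord <- order(d2)
    mols <- sys$molecule[cand[ord]]
    n_partner <- if (config$ecl_valence == "divalent") 1L else 2L
    pick_mols <- unique(mols)[seq_len(min(n_partner, length(unique(mols))))]
    if (length(pick_mols) < n_partner) shortfall <- shortfall + 1L
    for (pm in pick_mols) {
      partner <- cand[ord][mols == pm][1]
      key <- paste(min(e, partner), max(e, partner))
      if (key %in% existing) next
      existing <- c(existing, key)
      new_i <- c(new_i, e); new_j <- c(new_j, partner)
    }
  }
  if (length(new_i) > 0) {
    fibril$topology$bonds <- rbind(
      fibril$topology$bonds,
      data.frame(i = new_i, j = new_j, species = species, state = 0L,
                 stringsAsFactors = FALSE))
  }
  attr(fibril, "ecl_shortfall") <- shortfall
  fibril
}

#' Insert AGE cross-links
#'
#' Inserts exactly `round(n_age * n_molecules)` AGE bonds between helical
#' beads of different molecules within the capture radius. Telopeptide
#' ends (the four terminal beads of each molecule) and extension beads are
#' excluded as binding sites. For densities below one per molecule, host
#' molecules are drawn first, then sites on them; otherwise cross-links
#' are drawn uniformly from all eligible site pairs.
#'
#' @inheritParams insert_ecl
#' @return the fibril with AGE bonds added.
#' @export
insert_ages <- function(fibril, config, strict = FALSE) {
  check_stage(fibril, strict, "AGE cross-link")
  stopifnot(inherits(config, "crosslink_config"))
  n_mol <- fibril$n_molecules
  count <- round(config$n_age * n_mol)
  if (count == 0) return(fibril)
  set.seed(config$seed + 1L)
  sys <- fibril$system
  eligible <- which(sys$role == "helical")
  pairs <- cg_close_pairs(sys$pos[eligible, , drop = FALSE],
                          config$capture_radius)
  pi_ <- eligible[pairs[, 1] + 1L]
  pj_ <- eligible[pairs[, 2] + 1L]
  keep <- sys$molecule[pi_] != sys$molecule[pj_]
  pi_ <- pi_[keep]; pj_ <- pj_[keep]
  existing <- paste(pmin(fibril$topology$bonds$i, fibril$topology$bonds$j),
                    pmax(fibril$topology$bonds$i, fibril$topology$bonds$j))
  keys <- paste(pmin(pi_, pj_), pmax(pi_, pj_))
  fresh <- !(keys %in% existing) & !duplicated(keys)
  pi_ <- pi_[fresh]; pj_ <- pj_[fresh]
  if (count > length(pi_)) {
    stop("requested ", count, " AGE cross-links but only ", length(pi_),
         " distinct eligible site pairs are available")
  }
  if (config$n_age < 1) {
    hosts <- sample(sort(unique(sys$molecule[c(pi_, pj_)])), count)
    pick <- integer(0)
    for (h in hosts) {
      idx <- which(sys$molecule[pi_] == h | sys$molecule[pj_] == h)
      idx <- setdiff(idx, pick)
      if (length(idx) == 0) next
      pick <- c(pick, if (length(idx) == 1) idx else sample(idx, 1))
    }
  } else {
    pick <- sample.int(length(pi_), count)
  }
  fibril$topology$bonds <- rbind(
    fibril$topology$bonds,
    data.frame(i = pi_[pick], j = pj_[pick], species = "age", state = 0L,
               stringsAsFactors = FALSE))
  fibril
}

#' Cross-link census
#'
#' Exact bond counts by species and intact/broken state, plus per-molecule
#' densities.
#'
#' @param topology a fibril topology (or a `fibril` object).
#' @param n_molecules molecule count for the densities (taken from the
#'   fibril when one is supplied).
#' @return data.frame with `species`, `n_total`, `n_intact`, `n_broken`,
#'   `density`.
#' @export
crosslink_census <- function(topology, n_molecules = NULL) {
  if (inherits(topology, "fibril")) {
    n_molecules <- topology$n_molecules
    topology <- topology$topology
  }
  b <- topology$bonds
  out <- do.call(rbind, lapply(BOND_SPECIES, function(sp) {
    sel <- b$species == sp
    data.frame(species = sp, n_total = sum(sel),
               n_intact = sum(sel & b$state == 0L),
               n_broken = sum(sel & b$state > 0L),
               stringsAsFactors = FALSE)
  }))
  out$density <- if (is.null(n_molecules)) NA_real_ else out$n_total / n_molecules
  out
}

#' Export the cross-link set as a plain-text table
#'
#' Freezes the randomness of an insertion so a cross-link arrangement can
#' be re-applied to a rebuilt system with [apply_crosslinks()].
#'
#' @param fibril a cross-linked `fibril`.
#' @param path output path (tab-separated).
#' @export
write_crosslinks <- function(fibril, path) {
  b <- fibril$topology$bonds
  xl <- b[b$species %in% c("ecl_divalent", "ecl_trivalent", "age"), , drop = FALSE]
  xl$mol_i <- fibril$system$molecule[xl$i]
  xl$mol_j <- fibril$system$molecule[xl$j]
  utils::write.table(xl[, c("species", "i", "j", "mol_i", "mol_j")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-apply a frozen cross-link set
#'
#' @param fibril a `fibril` without cross-links.
#' @param path table written by [write_crosslinks()].
#' @export
apply_crosslinks <- function(fibril, path) {
  xl <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  fibril$topology$bonds <- rbind(
    fibril$topology$bonds,
    data.frame(i = xl$i, j = xl$j, species = xl$species, state = 0L,
               stringsAsFactors = FALSE))
  fibril
}
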