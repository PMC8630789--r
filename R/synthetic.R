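# Synthetic compound libraries and activation matrices with known ground
# truth. Compounds are assembled from ring-system scaffold templates joined
# by single bonds and decorated with acyclic substituents, so the true
# Bemis-Murcko framework of every molecule is known exactly by
# construction. Activation is Bernoulli per (compound, receptor) with
# receptor-specific probabilities and a long-tailed promiscuous compound
# type; all-zero rows are resampled because agonist datasets contain only
# agonists.

default_scaffold_templates <- function() {
  c(benzene        = "c1ccccc1",
    cyclohexane    = "C1CCCCC1",
    tetrahydropyran = "C1CCOCC1",
    cyclopentane   = "C1CCCC1",
    pyridine       = "c1ccncc1",
    pyrazine       = "c1cnccn1",
    thiophene      = "c1ccsc1",
    naphthalene    = "c1ccc2ccccc2c1",
    furan          = "c1ccoc1")
}

default_superclass_rule <- function() {
  c(benzene        = "Benzenoids",
    cyclohexane    = "Lipids and lipid-like molecules",
    tetrahydropyran = "Organic oxygen compounds",
    cyclopentane   = "Organic acids and derivatives",
    pyridine       = "Alkaloids and derivatives",
    pyrazine       = "Organoheterocyclic compounds",
    thiophene      = "Organosulfur compounds",
    naphthalene    = "Phenylpropanoids and polyketides",
    furan          = "Mixed metal/non-metal compounds")
}

#' Generator configuration
#'
#' Defaults emulate the structure of the curated food all-TAS2R-tested
#' agonist collection: 133 compounds, the 17 receptors with at least one
#' agonist in the published per-receptor table, and per-receptor activation
#' probabilities equal to the published agonist counts divided by 133
#' (giving a mean compound promiscuity near 2, with most compounds
#' activating one or two receptors).
#'
#' @param n_compounds number of compounds to generate.
#' @param p named per-receptor activation probability vector (names are
#'   receptor names or aliases); receptors of the universe not named get 0.
#' @param promiscuous_prob probability that a compound is promiscuous-type.
#' @param promiscuous_boost activation-rate multiplier for promiscuous-type
#'   compounds (capped at probability 1).
#' @param scaffold_templates named character vector of ring-system SMILES.
#' @param substituents character vector of acyclic SMILES fragments used as
#'   decorations (acyclic by requirement, so ground-truth frameworks are
#'   exact).
#' @param n_template_weights sampling weights for using 1, 2 or 3 scaffold
#'   templates per compound.
#' @param max_substituents maximum decorations per compound (0-3 drawn
#'   uniformly up to this).
#' @param superclass_rule named map template -> superclass label; templates
#'   without a rule yield "Unclassified".
#' @param seed integer seed; the whole generation is deterministic given it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 133,
                             p = NULL,
                             promiscuous_prob = 0.1,
                             promiscuous_boost = 3,
                             scaffold_templates = default_scaffold_templates(),
                             substituents = c("C", "CC", "CCC", "O", "N", "CO"),
                             n_template_weights = c(0.6, 0.3, 0.1),
                             max_substituents = 3,
                             superclass_rule = default_superclass_rule(),
                             seed = 1) {
  if (is.null(p)) {
    ref <- food_agonist_reference_counts()
    p <- stats::setNames(ref$n_compounds / 133, ref$receptor)
  }
  stopifnot(all(p >= 0 & p <= 1), length(scaffold_templates) > 0,
            length(substituents) > 0, promiscuous_prob >= 0, promiscuous_prob <= 1)
  names(p) <- resolve_receptor(names(p))
  # templates must contain at least one ring; substituents must be acyclic
  for (s in scaffold_templates) {
    if (!any(ring_bond_mask(parse_smiles(s)))) {
      stop_bitter("validation_error", sprintf("template without a ring: %s", s))
    }
  }
  for (s in substituents) {
    if (any(ring_bond_mask(parse_smiles(s)))) {
      stop_bitter("validation_error", sprintf("substituent contains a ring: %s", s))
    }
  }
  structure(list(n_compounds = as.integer(n_compounds), p = p,
                 promiscuous_prob = promiscuous_prob,
                 promiscuous_boost = promiscuous_boost,
                 scaffold_templates = scaffold_templates,
                 substituents = substituents,
                 n_template_weights = n_template_weights,
                 max_substituents = as.integer(max_substituents),
                 superclass_rule = superclass_rule,
                 seed = as.integer(seed)),
            class = "generator_config")
}

std_valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1)

free_valence_atoms <- function(mol) {
  used <- numeric(n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    used[mol$bonds$a1[k]] <- used[mol$bonds$a1[k]] + mol$bonds$order[k]
    used[mol$bonds$a2[k]] <- used[mol$bonds$a2[k]] + mol$bonds$order[k]
  }
  cap <- std_valence[mol$elem]
  cap[is.na(cap)] <- 0
  which(used < cap)
}

# join two graphs with a single bond between given atoms
join_mols <- function(a, b, atom_a, atom_b) {
  off <- n_atoms(a)
  bonds <- rbind(a$bonds,
                 data.frame(a1 = b$bonds$a1 + off, a2 = b$bonds$a2 + off,
                            order = b$bonds$order),
                 data.frame(a1 = atom_a, a2 = atom_b + off, order = 1L))
  new_mol(c(a$elem, b$elem), bonds)
}

#' Generate a synthetic compound library
#'
#' Each compound is one scaffold template (or 2-3 templates chained by
#' single bonds, recorded in the ground truth) decorated with 0-3 acyclic
#' substituents at free-valence positions. Emitted SMILES are OpenBabel
#' canonical and guaranteed to parse; assemblies that fail to produce a
#' valid molecule are rejected and resampled, with the resample count
#' recorded.
#'
#' @param cfg a [generator_config()].
#' @return List with `compounds` (data.frame of compound records, without
#'   superclass labels — see [assign_superclasses()]) and `truth`
#'   (data.frame with the true framework SMILES, templates used, and
#'   promiscuous-type flag; attribute `"resamples"` counts rejections).
#' @export
generate_compounds <- function(cfg) {
  set.seed(cfg$seed)
  tmpl_mols <- lapply(cfg$scaffold_templates, parse_smiles)
  sub_mols <- lapply(cfg$substituents, parse_smiles)
  n <- cfg$n_compounds
  recs <- vector("list", n)
  truths <- vector("list", n)
  resamples <- 0L
  for (i in seq_len(n)) {
    repeat {
      k <- sample.int(length(cfg$n_template_weights), 1,
                      prob = cfg$n_template_weights)
      which_t <- sample.int(length(tmpl_mols), k, replace = TRUE)
      scaf <- tmpl_mols[[which_t[1]]]
      ok <- TRUE
      if (k > 1) for (j in 2:k) {
        fa <- free_valence_atoms(scaf)
        nxt <- tmpl_mols[[which_t[j]]]
        fb <- free_valence_atoms(nxt)
        if (length(fa) == 0 || length(fb) == 0) { ok <- FALSE; break }
        scaf <- join_mols(scaf, nxt,
                          fa[sample.int(length(fa), 1)],
                          fb[sample.int(length(fb), 1)])
      }
      if (!ok) { resamples <- resamples + 1L; next }
      true_fw <- canonical_fragments(list(scaf))
      mol <- scaf
      nsub <- sample.int(cfg$max_substituents + 1L, 1) - 1L
      for (j in seq_len(nsub)) {
        fa <- free_valence_atoms(mol)
        if (length(fa) == 0) break
        sub <- sub_mols[[sample.int(length(sub_mols), 1)]]
        fb <- free_valence_atoms(sub)
        mol <- join_mols(mol, sub, fa[sample.int(length(fa), 1)],
                         fb[1])
      }
      smi <- canonical_fragments(list(mol))
      if (is.na(true_fw) || is.na(smi) || !smiles_parses(smi)) {
        resamples <- resamples + 1L
        next
      }
      id <- sprintf("SYN%04d", i)
      recs[[i]] <- data.frame(compound_id = id, name = id, smiles = smi,
                              superclass = NA_character_, is_food = TRUE,
                              tested_all_receptors = TRUE)
      truths[[i]] <- data.frame(compound_id = id, true_framework = true_fw,
                                templates = paste(names(cfg$scaffold_templates)[which_t],
                                                  collapse = "+"),
                                primary_template = names(cfg$scaffold_templates)[which_t[1]],
                                n_templates = k)
      break
    }
  }
  compounds <- do.call(rbind, recs)
  truth <- do.call(rbind, truths)
  attr(truth, "resamples") <- resamples
  list(compounds = compounds, truth = truth)
}

#' Assign superclass labels from the ground truth
#'
#' Applies the configured template -> superclass rule to each compound's
#' primary scaffold template; templates without a rule are labeled
#' `"Unclassified"` (and are excluded by `select_subset(ds, "classified")`
#' in superclass analyses).
#'
#' @param compounds compound data.frame from [generate_compounds()].
#' @param truth matching ground-truth data.frame.
#' @param cfg the [generator_config()].
#' @return The compound data.frame with `superclass` filled in.
#' @export
assign_superclasses <- function(compounds, truth, cfg) {
  stopifnot(identical(compounds$compound_id, truth$compound_id))
  lab <- unname(cfg$superclass_rule[truth$primary_template])
  compounds$superclass <- ifelse(is.na(lab), "Unclassified", lab)
  compounds
}

#' Generate a synthetic activation matrix
#'
#' Each (compound, receptor) entry is an independent Bernoulli draw with
#' the receptor's activation probability, multiplied by the promiscuity
#' boost (capped at 1) for promiscuous-type compounds. Rows that come out
#' all-zero are redrawn; the resample count is recorded as attribute
#' `"activity_resamples"` on the returned dataset, and the promiscuous-type
#' flags as attribute `"promiscuous_type"`.
#'
#' @param compounds compound data.frame (records to attach the matrix to).
#' @param cfg the [generator_config()].
#' @return An `activity_dataset`.
#' @export
generate_activity <- function(compounds, cfg) {
  set.seed(cfg$seed + 1L)
  n <- nrow(compounds)
  universe <- tas2r_universe()
  p_full <- stats::setNames(rep(0, length(universe)), universe)
  p_full[names(cfg$p)] <- cfg$p
  promiscuous <- stats::runif(n) < cfg$promiscuous_prob
  act <- matrix(0L, n, length(universe), dimnames = list(compounds$compound_id, universe))
  resamples <- 0L
  for (i in seq_len(n)) {
    pi_ <- if (promiscuous[i]) pmin(1, p_full * cfg$promiscuous_boost) else p_full
    repeat {
      row <- as.integer(stats::runif(length(pi_)) < pi_)
      if (sum(row) > 0 || all(pi_ == 0)) break
      resamples <- resamples + 1L
    }
    act[i, ] <- row
  }
  ds <- activity_dataset(compounds, act)
  attr(ds, "activity_resamples") <- resamples
  attr(ds, "promiscuous_type") <- stats::setNames(promiscuous, compounds$compound_id)
  ds
}

#' Generate a full synthetic dataset with ground truth
#'
#' Convenience composition of [generate_compounds()],
#' [assign_superclasses()] and [generate_activity()].
#'
#' @param cfg a [generator_config()].
#' @return List with `dataset` (an `activity_dataset`) and `truth`.
#' @export
synthesize_dataset <- function(cfg = generator_config()) {
  gen <- generate_compounds(cfg)
  gen$compounds <- assign_superclasses(gen$compounds, gen$truth, cfg)
  ds <- generate_activity(gen$compounds, cfg)
  list(dataset = ds, truth = gen$truth)
}
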