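# Energy-guided supercharging: fixed-backbone packing under adjusted
# charged-residue reference energies, and a ramp mode that lowers those
# reference energies step by step until a target net charge is reached.
# Also defines the shared design-result container used by both protocols.

#' Options for the energy-guided supercharging protocol
#'
#' Collects the protocol switches in one object. Defaults mirror the design
#' conventions of the method: all `include_*` flags off (the caller must
#' enable at least one charged type, which also fixes the polarity), the
#' atom-based surface definition with AvNAPSA cutoff 120 (residue-based
#' cutoff 16 when selected), and all three preservation rules on.
#'
#' @param include_arg,include_lys,include_asp,include_glu Charged residue
#'   types the packer may introduce. Positive types (R/K) and negative
#'   types (D/E) cannot be mixed.
#' @param surface_mode `"atom_based"` (AvNAPSA) or `"residue_based"`
#'   (Cbeta neighbor count).
#' @param surface_atom_cutoff,surface_residue_cutoff Surface cutoffs
#'   (strict `<`).
#' @param preserve_glyprocys,preserve_hbonded_sidechains,preserve_correct_charge
#'   Preservation rules, each individually defeatable.
#' @param pre_pack Repack the native side chains (no design) first, so
#'   energy comparisons use a relaxed baseline.
#' @param nstruct Number of independent packing runs (distinct seeds); the
#'   lowest-energy result is kept.
#' @param seed Master seed.
#' @param resfile Optional residue-file path restricting mutable positions.
#' @param design_chain Chain to design (default: first chain); other chains
#'   are fixed context.
#' @param schedule Annealing schedule, see [pack_rotamers()].
#' @return list of class `supercharge_options`.
#' @export
supercharge_options <- function(include_arg = FALSE, include_lys = FALSE,
                                include_asp = FALSE, include_glu = FALSE,
                                surface_mode = c("atom_based",
                                                 "residue_based"),
                                surface_atom_cutoff = 120,
                                surface_residue_cutoff = 16,
                                preserve_glyprocys = TRUE,
                                preserve_hbonded_sidechains = TRUE,
                                preserve_correct_charge = TRUE,
                                pre_pack = FALSE, nstruct = 1L, seed = 1L,
                                resfile = NULL, design_chain = NULL,
                                schedule = list(kT_hi = 10, kT_lo = 0.3,
                                                sweeps = 30)) {
  structure(list(include_arg = include_arg, include_lys = include_lys,
                 include_asp = include_asp, include_glu = include_glu,
                 surface_mode = match.arg(surface_mode),
                 surface_atom_cutoff = surface_atom_cutoff,
                 surface_residue_cutoff = surface_residue_cutoff,
                 preserve_glyprocys = preserve_glyprocys,
                 preserve_hbonded_sidechains = preserve_hbonded_sidechains,
                 preserve_correct_charge = preserve_correct_charge,
                 pre_pack = pre_pack, nstruct = as.integer(nstruct),
                 seed = as.integer(seed), resfile = resfile,
                 design_chain = design_chain, schedule = schedule),
            class = "supercharge_options")
}

.options_polarity <- function(options) {
  pos <- options$include_arg || options$include_lys
  neg <- options$include_asp || options$include_glu
  if (pos && neg)
    stop("cannot mix positive (R/K) and negative (D/E) included types",
         call. = FALSE)
  if (!pos && !neg)
    stop("enable at least one charged type via include_arg/include_lys/",
         "include_asp/include_glu", call. = FALSE)
  if (pos) "positive" else "negative"
}

.included_types <- function(options, polarity) {
  if (polarity == "positive")
    c(if (options$include_arg) "R", if (options$include_lys) "K")
  else c(if (options$include_asp) "D", if (options$include_glu) "E")
}

# Shared result container for both protocols.
.design_result <- function(native, designed, mutations = NULL, protocol,
                           polarity, model, final_reference_energies,
                           seed, max_avnapsa = NA_real_, ramp = NULL,
                           task = NULL) {
  default_model <- model
  default_model$reference_energies <- energy_model()$reference_energies
  sc_nat <- score_structure(native, default_model)
  sc_des <- score_structure(designed, default_model)
  seq_nat <- .sequence_by_key(native)
  seq_des <- .sequence_by_key(designed)
  diff_keys <- names(seq_nat)[seq_nat != seq_des]
  ann <- surface_annotation(native)
  if (is.null(mutations)) {
    rt <- residue_sites(native)
    ix <- match(diff_keys, rt$key)
    chg <- function(aa) ifelse(is.na(AA_FORMAL_CHARGE[aa]), 0L,
                               AA_FORMAL_CHARGE[aa])
    mutations <- data.frame(chain = rt$chain[ix], number = rt$number[ix],
                            icode = rt$icode[ix], key = diff_keys,
                            native_aa = unname(seq_nat[diff_keys]),
                            new_aa = unname(seq_des[diff_keys]),
                            charge_delta =
                              as.integer(chg(seq_des[diff_keys]) -
                                           chg(seq_nat[diff_keys])),
                            avnapsa = ann$avnapsa[match(diff_keys, ann$key)],
                            stringsAsFactors = FALSE)
  }
  mutations$energy_delta <- sc_des$per_residue$total[
    match(mutations$key, sc_des$per_residue$key)] -
    sc_nat$per_residue$total[match(mutations$key, sc_nat$per_residue$key)]
  energy_table <- data.frame(
    key = sc_nat$per_residue$key,
    aa_native = sc_nat$per_residue$aa,
    aa_designed = sc_des$per_residue$aa,
    total_native = sc_nat$per_residue$total,
    total_designed = sc_des$per_residue$total,
    delta = sc_des$per_residue$total - sc_nat$per_residue$total,
    mutated = sc_nat$per_residue$key %in% mutations$key,
    stringsAsFactors = FALSE)
  structure(list(structure = designed, native = native,
                 mutations = mutations,
                 net_charge_before = net_formal_charge(native),
                 net_charge_after = net_formal_charge(designed),
                 final_reference_energies = final_reference_energies,
                 protocol = protocol, polarity = polarity,
                 energy_table = energy_table,
                 max_avnapsa_of_mutations = max_avnapsa,
                 seed = seed, ramp = ramp, task = task),
            class = "supercharge_design")
}

#' @export
print.supercharge_design <- function(x, ...) {
  cat("supercharge design (", x$protocol, ", ", x$polarity, ")\n", sep = "")
  cat("net charge: ", sprintf("%+d", x$net_charge_before), " -> ",
      sprintf("%+d", x$net_charge_after), " (", nrow(x$mutations),
      " mutations)\n", sep = "")
  if (nrow(x$mutations))
    cat(paste0(x$mutations$native_aa, x$mutations$number,
               x$mutations$new_aa, collapse = ", "), "\n")
  invisible(x)
}

#' Energy-guided supercharging at given reference energies
#'
#' Classifies the surface, builds the design task with the preservation
#' rules, overrides the charged-residue reference energies with
#' `refweights`, and packs. More negative reference weights bias the packer
#' toward more charged mutations; the defaults give the low-charge regime
#' in which every accepted mutation must improve the model energy on its
#' own merits.
#'
#' @param structure A [protein_structure()].
#' @param refweights Named numeric vector of reference energies, names
#'   restricted to the charged types enabled in `options` (e.g.
#'   `c(K = -1.0)`); defaults to the model's stored values for the included
#'   types.
#' @param options A [supercharge_options()]; polarity is inferred from the
#'   `include_*` flags.
#' @param model An [energy_model()].
#' @param rotamers Rotamer library.
#' @return Object of class `supercharge_design` with fields `structure`,
#'   `native`, `mutations` (with per-mutation energy deltas), net charges
#'   before/after, `final_reference_energies`, `energy_table` (per-residue
#'   comparison at default reference energies), `protocol`, `polarity`,
#'   `seed`.
#' @export
supercharge_with_refweights <- function(structure, refweights = NULL,
                                        options = supercharge_options(),
                                        model = energy_model(),
                                        rotamers = default_rotamers()) {
  polarity <- .options_polarity(options)
  types <- .included_types(options, polarity)
  if (is.null(refweights))
    refweights <- model$reference_energies[types]
  if (length(setdiff(names(refweights), types)))
    stop("refweights given for types not enabled by the include_* options: ",
         paste(setdiff(names(refweights), types), collapse = ", "),
         call. = FALSE)
  design_model <- model
  design_model$reference_energies[names(refweights)] <- refweights
  mode <- options$surface_mode
  cutoff <- if (mode == "atom_based") options$surface_atom_cutoff
            else options$surface_residue_cutoff
  surface <- classify_surface(structure, mode, cutoff)
  chain <- options$design_chain
  if (is.null(chain)) chain <- residue_sites(structure)$chain[1]
  native <- structure
  if (isTRUE(options$pre_pack)) {
    repack_task <- build_design_task(
      structure, surface, polarity, model,
      preserve_glyprocys = options$preserve_glyprocys,
      preserve_hbonded_sidechains = options$preserve_hbonded_sidechains,
      preserve_correct_charge = options$preserve_correct_charge,
      resfile = options$resfile, design_chain = chain)
    native <- pack_rotamers(structure, repack_task, model,
                            seed = options$seed, schedule = options$schedule,
                            rotamers = rotamers)$structure
  }
  task <- build_design_task(
    native, surface, polarity, model,
    include_arg = options$include_arg, include_lys = options$include_lys,
    include_asp = options$include_asp, include_glu = options$include_glu,
    preserve_glyprocys = options$preserve_glyprocys,
    preserve_hbonded_sidechains = options$preserve_hbonded_sidechains,
    preserve_correct_charge = options$preserve_correct_charge,
    resfile = options$resfile, design_chain = chain)
  if (!any(task$designable)) {
    warning("no designable surface sites; returning the input unchanged",
            call. = FALSE)
    return(.design_result(native, native, protocol = "energy",
                          polarity = polarity, model = model,
                          final_reference_energies = refweights,
                          seed = options$seed, task = task))
  }
  seeds <- options$seed + seq_len(options$nstruct) - 1L
  best <- NULL
  for (s in seeds) {
    run <- pack_rotamers(native, task, design_model, seed = s,
                         schedule = options$schedule, rotamers = rotamers)
    if (is.null(best) || run$energy < best$energy) {
      best <- run
      best$seed <- s
    }
  }
  .design_result(native, best$structure, protocol = "energy",
                 polarity = polarity, model = model,
                 final_reference_energies = refweights, seed = best$seed,
                 task = task)
}

#' Energy-guided supercharging to a target net charge
#'
#' Starting from the default reference energies of the included charged
#' types, lowers them by `step` per iteration (both types of a polarity
#' move together, preserving their default offset) and re-packs from the
#' native structure with a fresh seed each iteration, until the net charge
#' reaches or passes `target_charge` or `max_iter` is hit. The returned
#' design records the final reference energies and the full ramp
#' trajectory.
#'
#' @param structure A [protein_structure()].
#' @param target_charge Desired net charge, strictly on the polarity's side
#'   of the current net charge.
#' @param options A [supercharge_options()].
#' @param model An [energy_model()].
#' @param rotamers Rotamer library.
#' @param step Reference-energy decrement per iteration (energy units).
#' @param max_iter Iteration cap.
#' @return A `supercharge_design` with an additional `ramp` data.frame
#'   (iteration, reference energies, achieved charge, mutation count).
#' @export
supercharge_to_target <- function(structure, target_charge,
                                  options = supercharge_options(),
                                  model = energy_model(),
                                  rotamers = default_rotamers(),
                                  step = 0.05, max_iter = 60L) {
  polarity <- .options_polarity(options)
  types <- .included_types(options, polarity)
  charge0 <- net_formal_charge(structure)
  if (polarity == "positive" && target_charge <= charge0)
    stop("target must be more positive than the current net charge",
         call. = FALSE)
  if (polarity == "negative" && target_charge >= charge0)
    stop("target must be more negative than the current net charge",
         call. = FALSE)
  base <- model$reference_energies[types]
  ramp <- list()
  best_result <- NULL
  best_reach <- charge0
  for (iter in 0:max_iter) {
    refs <- base - step * iter
    opt_i <- options
    opt_i$seed <- options$seed + iter
    res <- supercharge_with_refweights(structure, refs, opt_i, model,
                                       rotamers)
    achieved <- res$net_charge_after
    ramp[[length(ramp) + 1]] <-
      cbind(data.frame(iteration = iter), as.data.frame(as.list(refs)),
            data.frame(net_charge = achieved,
                       n_mutations = nrow(res$mutations)))
    further <- if (polarity == "positive") achieved > best_reach
               else achieved < best_reach
    if (is.null(best_result) || further) {
      best_result <- res
      best_reach <- achieved
    }
    reached <- if (polarity == "positive") achieved >= target_charge
               else achieved <= target_charge
    if (reached) {
      res$ramp <- do.call(rbind, ramp)
      return(res)
    }
  }
  .unreachable_charge(best_reach, target_charge,
                      extra = list(final_reference_energies =
                                     base - step * max_iter,
                                   ramp = do.call(rbind, ramp)))
}
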