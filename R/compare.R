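# Protocol-comparison statistics: overlap of mutated positions, per-term
# energy deltas at default reference energies, hydrogen bonds lost and
# gained (strong/weak), and mutational economy (mutations per unit of net
# charge).

#' Mutations per unit of net charge
#'
#' Number of mutations divided by the absolute net-charge change. Designs
#' made only of charge swaps (+/-2 per mutation) score 0.5; designs made
#' only of neutral-to-charged mutations score 1.0. The exposure-ranked
#' protocol, whose candidates include the +/-2 swaps first-class, typically
#' needs fewer mutations per charge than energy-guided design.
#'
#' @param result A `supercharge_design`.
#' @return Numeric ratio.
#' @export
mutations_per_charge <- function(result) {
  stopifnot(inherits(result, "supercharge_design"))
  d <- abs(result$net_charge_after - result$net_charge_before)
  if (d == 0) stop("undefined: design did not change the net charge",
                   call. = FALSE)
  nrow(result$mutations) / d
}

.hbond_id <- function(hb) {
  if (!nrow(hb)) return(character(0))
  paste(hb$donor_key, hb$donor_atom, hb$acceptor_key, hb$acceptor_atom,
        sep = "|")
}

.hbond_delta <- function(native_hb, design_hb, threshold) {
  strength <- function(hb) ifelse(hb$energy < threshold, "strong",
                                  ifelse(hb$energy < -0.1, "weak", "none"))
  nid <- .hbond_id(native_hb); did <- .hbond_id(design_hb)
  ns <- strength(native_hb); ds <- strength(design_hb)
  lost <- !(nid %in% did)
  gained <- !(did %in% nid)
  c(lost_strong = sum(lost & ns == "strong"),
    lost_weak = sum(lost & ns == "weak"),
    gained_strong = sum(gained & ds == "strong"),
    gained_weak = sum(gained & ds == "weak"))
}

#' Compare two designs of the same native structure
#'
#' Computes the shared-mutation statistics (fraction of mutated positions
#' shared, and shared with identical replacement type, both over the union
#' of mutated positions), per-term energy deltas scored at the *default*
#' reference energies regardless of design-time weights, and
#' strong/weak hydrogen bonds lost and gained relative to the native.
#'
#' @param native The common input [protein_structure()].
#' @param design_a,design_b `supercharge_design` objects derived from
#'   `native`.
#' @param model An [energy_model()]; its reference energies are reset to
#'   the defaults for the comparison scoring.
#' @return list of class `design_comparison`.
#' @export
compare_designs <- function(native, design_a, design_b,
                            model = energy_model()) {
  stopifnot(inherits(design_a, "supercharge_design"),
            inherits(design_b, "supercharge_design"))
  nat_seq <- .sequence_by_key(native)
  for (d in list(design_a, design_b)) {
    ds <- .sequence_by_key(d$native)
    if (!identical(nat_seq, ds))
      stop("designs do not derive from the given native structure",
           call. = FALSE)
  }
  cmp_model <- model
  cmp_model$reference_energies <- energy_model()$reference_energies
  pa <- design_a$mutations$key
  pb <- design_b$mutations$key
  uni <- union(pa, pb)
  shared <- intersect(pa, pb)
  type_a <- stats::setNames(design_a$mutations$new_aa, pa)
  type_b <- stats::setNames(design_b$mutations$new_aa, pb)
  shared_type <- shared[type_a[shared] == type_b[shared]]
  sc_nat <- score_structure(native, cmp_model)
  sc_a <- score_structure(design_a$structure, cmp_model)
  sc_b <- score_structure(design_b$structure, cmp_model)
  thr <- cmp_model$hbond_preserve_threshold
  hb_nat <- detect_sidechain_hbonds(native, cmp_model)
  hb_a <- detect_sidechain_hbonds(design_a$structure, cmp_model)
  hb_b <- detect_sidechain_hbonds(design_b$structure, cmp_model)
  structure(list(
    shared_positions = shared,
    shared_position_fraction = if (length(uni))
      length(shared) / length(uni) else 0,
    shared_position_and_type_fraction = if (length(uni))
      length(shared_type) / length(uni) else 0,
    mutations_a = length(pa), mutations_b = length(pb),
    energy_deltas_a = sc_a$terms - sc_nat$terms,
    energy_deltas_b = sc_b$terms - sc_nat$terms,
    hbond_delta_a = .hbond_delta(hb_nat, hb_a, thr),
    hbond_delta_b = .hbond_delta(hb_nat, hb_b, thr),
    mutations_per_charge_a = mutations_per_charge(design_a),
    mutations_per_charge_b = mutations_per_charge(design_b)),
    class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  cat("design comparison\n")
  cat(sprintf("  mutations: %d vs %d\n", x$mutations_a, x$mutations_b))
  cat(sprintf("  shared positions: %d (%.0f%%), same type %.0f%%\n",
              length(x$shared_positions),
              100 * x$shared_position_fraction,
              100 * x$shared_position_and_type_fraction))
  cat(sprintf("  mutations/charge: %.2f vs %.2f\n",
              x$mutations_per_charge_a, x$mutations_per_charge_b))
  cat("  hbonds lost (strong/weak): ",
      x$hbond_delta_a[["lost_strong"]], "/", x$hbond_delta_a[["lost_weak"]],
      " vs ", x$hbond_delta_b[["lost_strong"]], "/",
      x$hbond_delta_b[["lost_weak"]], "\n", sep = "")
  invisible(x)
}

#' Write a comparison report
#'
#' TSV table of the comparison statistics plus a human-readable text block.
#'
#' @param comparison A [compare_designs()] result.
#' @param path Output TSV path; a `.txt` sibling holds the text block.
#' @return Invisibly, `path`.
#' @export
write_comparison <- function(comparison, path) {
  tab <- data.frame(
    statistic = c("mutations_a", "mutations_b", "shared_positions",
                  "shared_position_fraction",
                  "shared_position_and_type_fraction",
                  "mutations_per_charge_a", "mutations_per_charge_b",
                  paste0("a_", names(comparison$hbond_delta_a)),
                  paste0("b_", names(comparison$hbond_delta_b)),
                  paste0("a_delta_", names(comparison$energy_deltas_a)),
                  paste0("b_delta_", names(comparison$energy_deltas_b))),
    value = c(comparison$mutations_a, comparison$mutations_b,
              length(comparison$shared_positions),
              comparison$shared_position_fraction,
              comparison$shared_position_and_type_fraction,
              comparison$mutations_per_charge_a,
              comparison$mutations_per_charge_b,
              unname(comparison$hbond_delta_a),
              unname(comparison$hbond_delta_b),
              unname(comparison$energy_deltas_a),
              unname(comparison$energy_deltas_b)),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- utils::capture.output(print(comparison))
  writeLines(txt, sub("\\.tsv$", ".txt", path))
  invisible(path)
}
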