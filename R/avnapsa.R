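# The deterministic exposure-ranked supercharging protocol: candidate
# polar/charged residues are sorted by AvNAPSA value (most exposed first)
# and force-mutated one by one until a target net charge is reached, or all
# candidates below a surface cutoff are taken. Positive supercharging uses
# D/E/N/Q -> K; negative uses R/K/Q -> E and N -> D. Arginine is never a
# designed type, and aspartate only appears where the native residue is
# asparagine.

.AVNAPSA_SWAPS <- list(
  positive = list(D = list(new = "K", delta = 2L),
                  E = list(new = "K", delta = 2L),
                  N = list(new = "K", delta = 1L),
                  Q = list(new = "K", delta = 1L)),
  negative = list(R = list(new = "E", delta = -2L),
                  K = list(new = "E", delta = -2L),
                  Q = list(new = "E", delta = -1L),
                  N = list(new = "D", delta = -1L))
)

.unreachable_charge <- function(best, target, extra = NULL) {
  cond <- structure(
    list(message = paste0("target net charge ", sprintf("%+d", target),
                          " unreachable; best achievable ",
                          sprintf("%+d", best)),
         call = NULL, best_achievable = best, target = target,
         extra = extra),
    class = c("unreachable_charge_error", "error", "condition"))
  stop(cond)
}

#' Ordered mutation candidates for the exposure-ranked protocol
#'
#' All N/Q plus D/E (positive polarity) or R/K (negative polarity) residues,
#' sorted ascending by AvNAPSA value (most solvent-exposed first), ties
#' broken by chain then residue number. Residues already carrying the
#' desired charge are not candidates.
#'
#' @param structure A [protein_structure()].
#' @param polarity `"positive"` or `"negative"`.
#' @param excluded Character vector of site keys to skip (e.g. from a
#'   residue file).
#' @param design_chain Restrict candidates to one chain (default first
#'   chain); other chains still contribute to neighbor counts.
#' @return data.frame, one row per candidate: site columns, `native_aa`,
#'   `new_aa`, `charge_delta`, `avnapsa`.
#' @export
candidate_list <- function(structure, polarity = c("positive", "negative"),
                           excluded = character(0), design_chain = NULL) {
  polarity <- match.arg(polarity)
  swaps <- .AVNAPSA_SWAPS[[polarity]]
  ann <- surface_annotation(structure)
  if (is.null(design_chain)) design_chain <- ann$chain[1]
  cand <- ann[ann$aa %in% names(swaps) & !(ann$key %in% excluded) &
                ann$chain %in% design_chain & !is.na(ann$avnapsa), ,
              drop = FALSE]
  if (!nrow(cand))
    return(data.frame(chain = character(0), number = integer(0),
                      icode = character(0), key = character(0),
                      native_aa = character(0), new_aa = character(0),
                      charge_delta = integer(0), avnapsa = numeric(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(chain = cand$chain, number = cand$number,
                    icode = cand$icode, key = cand$key,
                    native_aa = cand$aa,
                    new_aa = vapply(cand$aa, function(a) swaps[[a]]$new, ""),
                    charge_delta = vapply(cand$aa,
                                          function(a) swaps[[a]]$delta, 0L),
                    avnapsa = cand$avnapsa, stringsAsFactors = FALSE)
  out <- out[order(out$avnapsa, out$chain, out$number), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Choose mutations to reach a target net charge
#'
#' Takes the shortest prefix of the ordered candidate list whose cumulative
#' charge change moves `current_charge` to or past `target` (a +/-2 swap
#' crossing the target may overshoot by one unit). Errors if the candidates
#' are exhausted first, reporting the best achievable charge.
#'
#' @param candidates A [candidate_list()] result.
#' @param current_charge Net charge of the input structure.
#' @param target Desired net charge; must lie strictly on the polarity's
#'   side of `current_charge`.
#' @return The chosen candidate rows, with an `achieved_charge` attribute.
#' @export
choose_mutations_to_target <- function(candidates, current_charge, target) {
  if (!nrow(candidates))
    .unreachable_charge(current_charge, target)
  positive <- candidates$charge_delta[1] > 0
  if (positive && target <= current_charge)
    stop("target must be more positive than the current net charge",
         call. = FALSE)
  if (!positive && target >= current_charge)
    stop("target must be more negative than the current net charge",
         call. = FALSE)
  cum <- current_charge + cumsum(candidates$charge_delta)
  hit <- if (positive) which(cum >= target) else which(cum <= target)
  if (!length(hit))
    .unreachable_charge(cum[length(cum)], target)
  k <- hit[1]
  out <- candidates[seq_len(k), , drop = FALSE]
  attr(out, "achieved_charge") <- cum[k]
  out
}

#' Choose mutations by AvNAPSA surface cutoff
#'
#' All candidates with AvNAPSA value strictly below `cutoff`. Historical
#' usage: below 150 for aggressive supercharging, below 100 for moderate.
#'
#' @param candidates A [candidate_list()] result.
#' @param cutoff Positive AvNAPSA cutoff.
#' @return The chosen candidate rows.
#' @export
choose_mutations_by_cutoff <- function(candidates, cutoff) {
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("cutoff must be positive", call. = FALSE)
  candidates[candidates$avnapsa < cutoff, , drop = FALSE]
}

#' Run the exposure-ranked (AvNAPSA) supercharging protocol
#'
#' Sorts candidates by exposure, selects them by target net charge or by
#' surface cutoff (exactly one of the two), and force-mutates each selected
#' site with the lowest-clash rotamer of the replacement type. The result
#' records the mutation list with AvNAPSA values, the achieved net charge,
#' and the largest AvNAPSA value among mutated residues (used in output
#' naming).
#'
#' @param structure A [protein_structure()].
#' @param polarity `"positive"` or `"negative"`.
#' @param target_charge Desired net charge (mutually exclusive with
#'   `cutoff`).
#' @param cutoff AvNAPSA surface cutoff (mutually exclusive with
#'   `target_charge`).
#' @param resfile Optional residue file; `NATRO` positions are excluded, and
#'   `PIKAA` positions are excluded when the replacement type is not in the
#'   allowed set.
#' @param design_chain Chain to design (default first); other chains are
#'   fixed context.
#' @param model Energy model used for clash scoring and the result's energy
#'   comparison table.
#' @param rotamers Rotamer library for side-chain placement.
#' @return A `supercharge_design` object; see [supercharge_with_refweights()]
#'   for the shared fields.
#' @export
apply_avnapsa_design <- function(structure,
                                 polarity = c("positive", "negative"),
                                 target_charge = NULL, cutoff = NULL,
                                 resfile = NULL, design_chain = NULL,
                                 model = energy_model(),
                                 rotamers = default_rotamers()) {
  polarity <- match.arg(polarity)
  if (is.null(target_charge) == is.null(cutoff))
    stop("give exactly one of target_charge or cutoff", call. = FALSE)
  excluded <- character(0)
  allowed_override <- NULL
  if (!is.null(resfile)) {
    rf <- read_resfile(resfile)
    keys <- .site_key(rf$chain, rf$number)
    excluded <- keys[rf$mode == "NATRO"]
    allowed_override <- stats::setNames(rf$aas, keys)[rf$mode == "PIKAA"]
  }
  cand <- candidate_list(structure, polarity, excluded = excluded,
                         design_chain = design_chain)
  if (!is.null(allowed_override) && nrow(cand)) {
    drop <- vapply(seq_len(nrow(cand)), function(i) {
      al <- allowed_override[cand$key[i]]
      !is.na(al) && !grepl(cand$new_aa[i], al, fixed = TRUE)
    }, logical(1))
    cand <- cand[!drop, , drop = FALSE]
  }
  charge0 <- net_formal_charge(structure)
  chosen <- if (!is.null(target_charge))
    choose_mutations_to_target(cand, charge0, target_charge)
  else choose_mutations_by_cutoff(cand, cutoff)
  designed <- structure
  for (i in seq_len(nrow(chosen)))
    designed <- mutate_residue(designed, chosen$key[i], chosen$new_aa[i],
                               rotamers, model)
  .design_result(native = structure, designed = designed,
                 mutations = chosen, protocol = "avnapsa",
                 polarity = polarity, model = model,
                 final_reference_energies = NULL, seed = NA_integer_,
                 max_avnapsa = if (nrow(chosen)) max(chosen$avnapsa) else
                   NA_real_)
}
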