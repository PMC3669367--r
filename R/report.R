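# Deliverable outputs of a design run: the plain-text log (surface sites,
# charged-residue counts, net charge, mutation list, PyMOL selection,
# optional per-residue energy table), the residue file, and the
# self-documenting output PDB name.

#' PyMOL selection string for a design's mutations
#'
#' One clause per chain, residue numbers ascending, e.g.
#' `select mutations, chain A and resi 7+12`. Without mutations the
#' selection is `none`.
#'
#' @param result A `supercharge_design`.
#' @return Character scalar.
#' @export
pymol_selection <- function(result) {
  stopifnot(inherits(result, "supercharge_design"))
  m <- result$mutations
  if (!nrow(m)) return("select mutations, none")
  chains <- sort(unique(m$chain))
  clauses <- vapply(chains, function(ch) {
    nums <- sort(unique(m$number[m$chain == ch]))
    paste0("chain ", ch, " and resi ", paste(nums, collapse = "+"))
  }, character(1))
  paste0("select mutations, ", paste(clauses, collapse = " or "))
}

.fmt_signed <- function(x) sprintf("%+d", x)

#' Self-documenting output PDB name
#'
#' Energy-mode designs are named with the final reference energies and net
#' charge (`<input>_R<ref1>_<ref2>_netq<charge>.pdb`); exposure-ranked
#' designs with the net charge and the largest AvNAPSA value among the
#' mutated residues (`<input>_A_netq<charge>_avn<value>.pdb`). Signs are
#' always explicit.
#'
#' @param result A `supercharge_design`.
#' @param input_name Base name of the input structure (default: the
#'   native's source name).
#' @return File name string.
#' @export
output_name <- function(result, input_name = result$native$source_name) {
  stopifnot(inherits(result, "supercharge_design"))
  q <- .fmt_signed(result$net_charge_after)
  if (result$protocol == "avnapsa") {
    avn <- result$max_avnapsa_of_mutations
    avn_s <- if (is.na(avn)) "NA" else sprintf("%d", as.integer(round(avn)))
    return(paste0(input_name, "_A_netq", q, "_avn", avn_s, ".pdb"))
  }
  refs <- result$final_reference_energies
  ref_s <- paste(sprintf("%+.2f", unname(refs)), collapse = "_")
  paste0(input_name, "_R", ref_s, "_netq", q, ".pdb")
}

#' Write the design log
#'
#' Line-oriented plain-text log with fixed section headers, in order: the
#' invocation line, the surface site list, the count of each charged
#' residue type in the final sequence, the net charge, the mutation list,
#' the PyMOL selection, and optionally a per-residue energy comparison
#' (all residues or mutated positions only).
#'
#' @param result A `supercharge_design`.
#' @param path Output path.
#' @param command Invocation line to record (default: a reconstruction from
#'   the result's metadata).
#' @param compare_residue_energies_all Include the energy table for every
#'   residue.
#' @param compare_residue_energies_mut Include the energy table for mutated
#'   residues only (ignored when `compare_residue_energies_all` is set).
#' @param surface Character vector of surface site keys to record; default
#'   recomputes the atom-based surface of the native structure.
#' @return Invisibly, `path`.
#' @export
write_design_log <- function(result, path, command = NULL,
                             compare_residue_energies_all = FALSE,
                             compare_residue_energies_mut = TRUE,
                             surface = NULL) {
  stopifnot(inherits(result, "supercharge_design"))
  if (is.null(command))
    command <- paste0("supercharge --mode ", result$protocol,
                      " --polarity ", result$polarity,
                      " --input ", result$native$source_name)
  if (is.null(surface))
    surface <- classify_surface(result$native, "atom_based", 120)
  seq_des <- .sequence_by_key(result$structure)
  counts <- vapply(c("R", "K", "D", "E"), function(a) sum(seq_des == a),
                   integer(1))
  m <- result$mutations
  lines <- c(
    "# supercharge design log",
    paste0("command: ", command),
    "[surface]",
    paste0("sites: ", paste(surface, collapse = " ")),
    "[charged residue counts]",
    paste0(names(counts), ": ", counts),
    "[net charge]",
    paste0("net_charge_before: ", .fmt_signed(result$net_charge_before)),
    paste0("net_charge: ", .fmt_signed(result$net_charge_after)),
    "[mutations]",
    paste0("n_mutations: ", nrow(m)))
  if (nrow(m))
    lines <- c(lines, paste0("mutation: ", m$native_aa, " ", m$key, " ",
                             m$new_aa))
  lines <- c(lines, "[pymol]", pymol_selection(result))
  if (compare_residue_energies_all || compare_residue_energies_mut) {
    tab <- result$energy_table
    if (!compare_residue_energies_all)
      tab <- tab[tab$mutated, , drop = FALSE]
    lines <- c(lines, "[residue energies]",
               paste("key", "aa_native", "aa_designed", "total_native",
                     "total_designed", "delta", sep = "\t"))
    if (nrow(tab))
      lines <- c(lines, paste(tab$key, tab$aa_native, tab$aa_designed,
                              sprintf("%.4f", tab$total_native),
                              sprintf("%.4f", tab$total_designed),
                              sprintf("%.4f", tab$delta), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse the mutation list back out of a design log
#'
#' @param path Path to a log written by [write_design_log()].
#' @return data.frame with `native_aa`, `key`, `new_aa`.
#' @export
read_design_log_mutations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  m <- lines[startsWith(lines, "mutation: ")]
  if (!length(m))
    return(data.frame(native_aa = character(0), key = character(0),
                      new_aa = character(0), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(sub("^mutation: ", "", m), " "))
  data.frame(native_aa = f[, 1], key = f[, 2], new_aa = f[, 3],
             stringsAsFactors = FALSE)
}

#' Write all deliverables of a design run
#'
#' Writes the log, the residue file that governed the run (when the task is
#' available), and the output PDB with its self-documenting name into
#' `out_dir`.
#'
#' @param result A `supercharge_design`.
#' @param out_dir Output directory (created if missing).
#' @param prefix Base name for the outputs (default: input name).
#' @param ... Passed to [write_design_log()].
#' @return Named character vector of the files written.
#' @export
write_design_outputs <- function(result, out_dir = ".",
                                 prefix = result$native$source_name, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(out_dir, output_name(result, prefix))
  write_pdb(result$structure, pdb)
  log <- file.path(out_dir, paste0(prefix, "_design.log"))
  write_design_log(result, log, ...)
  files <- c(pdb = pdb, log = log)
  if (!is.null(result$task)) {
    rf <- file.path(out_dir, paste0(prefix, ".resfile"))
    write_resfile(result$task, rf)
    files <- c(files, resfile = rf)
  }
  files
}
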