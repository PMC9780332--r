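# Sequence-level charge model and cationic tag designer.
#
# Charge convention (documented choice): integer side-chain charges at
# neutral pH -- K/R = +1, D/E = -1, everything else (including H) 0; termini
# and chromophore ignored. Under this convention sfGFP computes to -7 and a
# 6xHis tag is charge-neutral.

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' The cationic tag repeat unit
#'
#' One repeat of the nine-residue cationic tag, GGSKKRKKR, carrying a net
#' charge of +6 (4 lysines + 2 arginines). Tags are built as `n` concatenated
#' repeats.
#'
#' @return A single string, the 9-mer repeat unit.
#' @export
#' @examples
#' tag_unit()
#' net_charge(tag_unit())
tag_unit <- function() "GGSKKRKKR"

#' Build a cationic tag of n repeats
#'
#' @param n_repeats Number of repeats of [tag_unit()], a non-negative integer.
#' @return A string of `9 * n_repeats` residues (empty string for 0 repeats).
#' @export
tag_sequence <- function(n_repeats) {
  if (length(n_repeats) != 1 || is.na(n_repeats) || n_repeats < 0 ||
      n_repeats != round(n_repeats)) {
    ct_stop("n_repeats must be a single non-negative integer",
            "invalid_argument")
  }
  strrep(tag_unit(), n_repeats)
}

#' Construct a validated protein sequence
#'
#' @param residues String over the 20-letter amino-acid alphabet (upper case,
#'   no gaps).
#' @param id Free-text identifier.
#' @param permissive If `TRUE`, non-canonical letters (X, B, Z, U, ...) are
#'   tolerated (they carry charge 0) with a warning instead of an error.
#' @return A `protein_sequence` object.
#' @export
protein_sequence <- function(residues, id = "seq", permissive = FALSE) {
  if (length(residues) != 1 || is.na(residues) || !nzchar(residues)) {
    ct_stop("empty sequence", "empty_input")
  }
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!(chars %in% AA_CANONICAL))
  if (length(bad)) {
    msg <- sprintf("non-canonical residue '%s' at position %d in '%s'",
                   chars[bad[1]], bad[1], id)
    if (permissive) ct_warn(msg, "noncanonical_residue")
    else ct_stop(msg, "invalid_residue")
  }
  structure(list(id = id, residues = residues), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s: %d aa, net charge %+d\n",
              x$id, nchar(x$residues), net_charge(x)))
  invisible(x)
}

#' Side-chain charge of one amino-acid letter
#'
#' +1 for K and R, -1 for D and E, 0 otherwise (H neutral, termini ignored).
#'
#' @param aa A single canonical amino-acid letter (vectorised).
#' @return Integer charge(s) in \{-1, 0, +1\}.
#' @export
#' @examples
#' residue_charge("K")  # +1
#' residue_charge("E")  # -1
residue_charge <- function(aa) {
  bad <- which(!(aa %in% AA_CANONICAL))
  if (length(bad)) {
    ct_stop(sprintf("non-canonical residue '%s' at position %d",
                    aa[bad[1]], bad[1]), "invalid_residue")
  }
  ifelse(aa %in% c("K", "R"), 1L, ifelse(aa %in% c("D", "E"), -1L, 0L))
}

as_residue_string <- function(seq) {
  if (inherits(seq, "protein_sequence")) seq$residues
  else if (is.character(seq) && length(seq) == 1) seq
  else ct_stop("expected a protein_sequence or a single string",
               "invalid_argument")
}

#' Net charge of a protein sequence
#'
#' Sum of side-chain charges; additive over concatenation.
#'
#' @param seq A `protein_sequence` or a plain string.
#' @param permissive Map non-canonical letters to charge 0 (with a warning)
#'   instead of erroring.
#' @return Integer net charge in elementary charges at neutral pH.
#' @export
#' @examples
#' net_charge("GGSKKRKKR")  # +6 per tag repeat
net_charge <- function(seq, permissive = FALSE) {
  s <- as_residue_string(seq)
  if (!nzchar(s) || is.na(s)) ct_stop("empty sequence", "empty_input")
  chars <- strsplit(s, "")[[1]]
  bad <- which(!(chars %in% AA_CANONICAL))
  if (length(bad)) {
    msg <- sprintf("non-canonical residue '%s' at position %d",
                   chars[bad[1]], bad[1])
    if (permissive) {
      ct_warn(msg, "noncanonical_residue")
      chars <- chars[-bad]
      if (!length(chars)) return(0L)
    } else {
      ct_stop(msg, "invalid_residue")
    }
  }
  sum(residue_charge(chars))
}

#' Per-residue charge profile
#'
#' @inheritParams net_charge
#' @return A `charge_profile`: sequence id, integer `net_charge` and the
#'   aligned vector of per-residue charges.
#' @export
charge_profile <- function(seq) {
  s <- as_residue_string(seq)
  if (!nzchar(s)) ct_stop("empty sequence", "empty_input")
  per <- residue_charge(strsplit(s, "")[[1]])
  structure(list(
    sequence_id = if (inherits(seq, "protein_sequence")) seq$id else "seq",
    net_charge = sum(per),
    per_residue_charges = per
  ), class = "charge_profile")
}

#' Predicted net charge of a tagged fusion
#'
#' A fusion is globular domain + `linker_lysines` lysines + `n_repeats` tag
#' repeats appended at the C-terminus; each repeat adds the repeat charge
#' (+6 for GGSKKRKKR) and each linker lysine +1.
#'
#' @param domain_charge Integer net charge of the globular domain.
#' @param n_repeats Number of tag repeats (>= 0).
#' @param linker_lysines Number of lysines inserted between domain and tag
#'   (>= 0).
#' @param repeat_charge Charge of one repeat; computed from the repeat unit
#'   sequence by default.
#' @return Integer fusion net charge.
#' @export
#' @examples
#' fusion_charge(-7, 2, 1)  # sfGFP-tag2 -> +6
#' fusion_charge(+6, 3, 0)  # GFP(+6)-tag3 -> +24
fusion_charge <- function(domain_charge, n_repeats, linker_lysines = 0,
                          repeat_charge = net_charge(tag_unit())) {
  if (any(c(n_repeats, linker_lysines) < 0) ||
      n_repeats != round(n_repeats) || linker_lysines != round(linker_lysines)) {
    ct_stop("n_repeats and linker_lysines must be non-negative integers",
            "invalid_argument")
  }
  as.integer(domain_charge + linker_lysines + repeat_charge * n_repeats)
}

#' Design a cationic tag for a globular domain
#'
#' Chooses the smallest number of tag repeats (plus 0-5 linker lysines) so
#' that the fusion net charge lands exactly on +6 (transient mode: the
#' phase-separation threshold, where condensates form and later disassemble)
#' or exactly on the smallest achievable value at or above
#' `persistent_target` (persistent mode; default +12, the charge at and
#' above which condensates form and persist).
#'
#' @param domain A `protein_sequence`, a plain sequence string, or a bare
#'   integer domain charge (in which case no fusion peptide is emitted).
#' @param mode `"transient"` or `"persistent"`.
#' @param persistent_target Target fusion charge for persistent mode; must
#'   exceed +6.
#' @param max_linker Maximum number of linker lysines considered (default 5).
#' @return A `tag_design` with fields `n_repeats`, `linker_lysines`,
#'   `predicted_fusion_charge`, `behavior_class`, and `fusion_peptide` (NA
#'   when only a domain charge was supplied).
#' @export
#' @examples
#' design_tag(-7, "transient")            # sfGFP-like: 2 repeats + 1 lysine
#' design_tag(+6, "persistent")           # 1 repeat -> +12
design_tag <- function(domain, mode = c("transient", "persistent"),
                       persistent_target = 12L, max_linker = 5L) {
  mode <- match.arg(mode)
  if (is.numeric(domain) && length(domain) == 1) {
    dc <- as.integer(domain)
    dom_res <- NA_character_
    dom_id <- sprintf("domain(%+d)", dc)
  } else {
    dom_res <- as_residue_string(domain)
    dc <- net_charge(dom_res)
    dom_id <- if (inherits(domain, "protein_sequence")) domain$id else "domain"
  }
  rc <- net_charge(tag_unit())  # +6

  if (mode == "transient") {
    target <- 6L
    if (dc > target) {
      ct_stop(sprintf(
        "transient design infeasible: domain charge %+d already exceeds +6 and repeats/linkers only add positive charge",
        dc), "infeasible_design")
    }
  } else {
    if (persistent_target <= 6) {
      ct_stop("persistent_target must exceed +6", "invalid_argument")
    }
    # achievable charges are every integer >= dc, so land on the smallest
    # achievable value at or above the target
    target <- as.integer(max(persistent_target, dc))
  }
  need <- target - dc
  linker <- need %% rc
  if (linker > max_linker) {
    ct_stop(sprintf(
      "design needs %d linker lysines but max_linker is %d", linker, max_linker),
      "infeasible_design")
  }
  n <- (need - linker) %/% rc

  peptide <- if (is.na(dom_res)) NA_character_ else
    paste0(dom_res, strrep("K", linker), tag_sequence(n))
  structure(list(
    domain_id = dom_id,
    domain_charge = dc,
    n_repeats = as.integer(n),
    linker_lysines = as.integer(linker),
    predicted_fusion_charge = fusion_charge(dc, n, linker),
    behavior_class = if (mode == "transient") "transient" else "persistent",
    fusion_peptide = peptide
  ), class = "tag_design")
}

#' @export
print.tag_design <- function(x, ...) {
  cat(sprintf(
    "<tag_design> %s (%+d) + %dx K + [%s]%d -> predicted %+d (%s)\n",
    x$domain_id, x$domain_charge, x$linker_lysines, tag_unit(), x$n_repeats,
    x$predicted_fusion_charge, x$behavior_class))
  invisible(x)
}

#' Net-charge distribution of a set of sequences
#'
#' Computes per-entry net charges and their empirical cumulative
#' distribution, e.g. over a whole proteome. Records containing
#' non-canonical residues are skipped with a warning and counted.
#'
#' @param records A named character vector of sequences, a list of
#'   `protein_sequence` objects, or a `Biostrings::AAStringSet`.
#' @return A `charge_distribution` with integer `charges` (one per retained
#'   entry), a step `cdf` (data.frame charge, cumulative_fraction) and the
#'   number of skipped records.
#' @export
proteome_charge_distribution <- function(records) {
  if (inherits(records, "AAStringSet")) {
    records <- setNames(as.character(records), names(records))
  }
  if (is.list(records)) {
    nm <- vapply(records, function(r)
      if (inherits(r, "protein_sequence")) r$id else NA_character_, "")
    records <- setNames(vapply(records, as_residue_string, ""), nm)
  }
  if (!length(records)) ct_stop("no records", "empty_input")
  charges <- rep(NA_integer_, length(records))
  for (i in seq_along(records)) {
    ch <- tryCatch(net_charge(records[[i]]), condentag_error = function(e) NA)
    charges[i] <- ch
  }
  skipped <- sum(is.na(charges))
  if (skipped == length(records)) {
    ct_stop("all records invalid", "empty_input")
  }
  if (skipped > 0) {
    ct_warn(sprintf("skipped %d invalid record(s)", skipped),
            "invalid_records_skipped")
  }
  keep <- !is.na(charges)
  charges <- setNames(as.integer(charges[keep]), names(records)[keep])
  lev <- sort(unique(charges))
  cdf <- data.frame(
    charge = lev,
    cumulative_fraction = vapply(lev, function(l) mean(charges <= l), 0.0)
  )
  structure(list(charges = charges, cdf = cdf, n_skipped = skipped),
            class = "charge_distribution")
}

#' @export
print.charge_distribution <- function(x, ...) {
  cat(sprintf(
    "<charge_distribution> %d entries, charges %d..%d, median %d (%d skipped)\n",
    length(x$charges), min(x$charges), max(x$charges),
    as.integer(median(x$charges)), x$n_skipped))
  invisible(x)
}

#' Fraction of entries with net charge inside a window
#'
#' @param dist A `charge_distribution`.
#' @param lo,hi Inclusive window bounds (may be infinite).
#' @return Fraction in `[0, 1]` of entries with `lo <= charge <= hi`.
#' @export
#' @examples
#' d <- proteome_charge_distribution(c(a = "DDDDDDD", b = "GGG", c = "GGSKKRKKR"))
#' fraction_in_window(d, -6, 6)  # 2/3
fraction_in_window <- function(dist, lo, hi) {
  stopifnot(inherits(dist, "charge_distribution"))
  if (lo > hi) ct_stop("lo must not exceed hi", "invalid_argument")
  mean(dist$charges >= lo & dist$charges <= hi)
}

#' Read protein sequences from a FASTA file
#'
#' Multi-record, wrapped-line FASTA via Biostrings.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) ct_stop(paste0("no such file: ", path),
                                  "missing_input")
  x <- Biostrings::readAAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write a per-sequence charge table
#'
#' @param records As in [proteome_charge_distribution()].
#' @param path Output CSV path (columns id, length, net_charge).
#' @return The table, invisibly.
#' @export
write_charge_table <- function(records, path) {
  if (inherits(records, "AAStringSet")) {
    records <- setNames(as.character(records), names(records))
  }
  tab <- data.frame(
    id = if (is.null(names(records))) sprintf("seq%d", seq_along(records))
         else names(records),
    length = nchar(unname(records)),
    net_charge = vapply(unname(records), net_charge, integer(1),
                        USE.NAMES = FALSE)
  )
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
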