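# Resolve the protein-subunit -> ligand-subunit pairing. Defaults to
# same-chain; an explicit named map (names = protein subunits) overrides,
# which is needed for inter-subunit binding sites.
resolve_pairing <- function(protein_subunits, lig_subunits, pairing) {
  if (is.null(pairing)) {
    missing <- setdiff(protein_subunits, lig_subunits)
    if (length(missing) > 0)
      stop("ligand subunits do not match protein subunits (",
           paste(missing, collapse = ","),
           " have no same-chain ligand); supply an explicit pairing map")
    return(setNames(protein_subunits, protein_subunits))
  }
  if (is.null(names(pairing)) || !all(protein_subunits %in% names(pairing)))
    stop("pairing map must name every protein subunit")
  if (!all(pairing[protein_subunits] %in% lig_subunits))
    stop("pairing map refers to subunits without ligand residues")
  pairing[protein_subunits]
}

# Per-subunit grouping of sidechain heavy atoms by residue. Returns, per
# subunit: atom index vector, parallel residue-group id vector, and the
# residue table (residue_seq, residue_name). Glycine-like residues without
# sidechain heavy atoms are absent and can never register contact.
sidechain_groups <- function(top) {
  subs <- subunit_ids(top)
  prot_subs <- subs[vapply(subs, function(s)
    any(top$subunit_id == s & top$category %in% c("protein_backbone", "protein_sidechain")),
    logical(1))]
  groups <- lapply(prot_subs, function(s) {
    idx <- which(top$subunit_id == s & top$category == "protein_sidechain" &
                   !top$is_hydrogen)
    key <- top$residue_seq[idx]
    res <- unique(data.frame(residue_seq = top$residue_seq[idx],
                             residue_name = top$residue_name[idx],
                             stringsAsFactors = FALSE))
    res <- res[order(res$residue_seq), , drop = FALSE]
    list(idx = idx, group = match(key, res$residue_seq), residues = res)
  })
  names(groups) <- prot_subs
  groups
}

residue_key <- function(residue_seq, residue_name) paste0(residue_name, residue_seq)

#' Per-residue contact frequencies against a ligand headgroup
#'
#' For each frame, subunit, and protein residue, the residue is "in contact"
#' in that frame iff the minimum distance between any of its sidechain heavy
#' atoms and any heavy headgroup atom of that subunit's ligand is less than
#' or equal to `cutoff` (closed boundary). Per-subunit frequencies are
#' contact-frame counts divided by the number of frames; the subunit-combined
#' value is either the arithmetic mean of per-subunit frequencies
#' (`subunit_mean`, the default) or the pooled fraction over all
#' subunit-frames (`frame_pooled`).
#'
#' Hydrogens and backbone atoms never participate; residues without
#' sidechain heavy atoms (glycine) can never register contact.
#'
#' @param ens an [ensemble()].
#' @param ligand a [ligand_spec()].
#' @param cutoff contact cutoff in Angstrom (default 5.0).
#' @param combine_mode `"subunit_mean"` or `"frame_pooled"`.
#' @param pairing optional named map protein subunit -> ligand subunit
#'   (default: same chain).
#' @param method neighbor-search method passed to [atoms_within_cutoff()].
#' @return an object of class `contact_profile` with elements
#'   `ligand_label`, `cutoff`, `n_frames`, `combine_mode`, `per_subunit`
#'   (data frame: residue_seq, residue_name, subunit_id, frequency) and
#'   `combined` (residue_seq, residue_name, frequency). Residues with zero
#'   contacts in all frames are omitted from the tables; query them with
#'   [contact_frequency()], which reports 0.
#' @export
contact_frequencies <- function(ens, ligand, cutoff = 5.0,
                                combine_mode = c("subunit_mean", "frame_pooled"),
                                pairing = NULL, method = "auto") {
  combine_mode <- match.arg(combine_mode)
  top <- ens$topology
  check_ligand_resolves(top, ligand)
  grp <- sidechain_groups(top)
  if (length(grp) == 0 || all(vapply(grp, function(g) length(g$idx), integer(1)) == 0))
    stop("ensemble has no protein sidechain heavy atoms")
  pair <- resolve_pairing(names(grp), ligand_subunits(ligand), pairing)
  hg_idx <- lapply(pair, function(ls) ligand_atom_idx(top, ligand, ls, headgroup_only = TRUE))
  nT <- n_frames(ens)
  subs <- names(grp)

  # union residue table across subunits, keyed by (residue_seq, residue_name)
  all_res <- unique(do.call(rbind, lapply(grp, `[[`, "residues")))
  all_res <- all_res[order(all_res$residue_seq), , drop = FALSE]
  keys <- residue_key(all_res$residue_seq, all_res$residue_name)
  counts <- matrix(0L, nrow(all_res), length(subs), dimnames = list(keys, subs))
  present <- matrix(FALSE, nrow(all_res), length(subs), dimnames = list(keys, subs))

  for (s in subs) {
    g <- grp[[s]]
    if (length(g$idx) == 0) next
    skey <- residue_key(g$residues$residue_seq, g$residues$residue_name)
    present[skey, s] <- TRUE
    href <- hg_idx[[s]]
    for (f in seq_len(nT)) {
      q <- ens$coords[g$idx, , f, drop = FALSE][, , 1, drop = FALSE]
      dim(q) <- c(length(g$idx), 3)
      r <- ens$coords[href, , f, drop = FALSE][, , 1, drop = FALSE]
      dim(r) <- c(length(href), 3)
      hit <- atoms_within_cutoff(q, r, cutoff, method = method)
      if (any(hit)) {
        touched <- unique(g$group[hit])
        counts[skey[touched], s] <- counts[skey[touched], s] + 1L
      }
    }
  }

  freq <- counts / nT
  n_sub <- rowSums(present)
  combined_val <- if (combine_mode == "subunit_mean") {
    rowSums(freq * present) / pmax(n_sub, 1)
  } else {
    rowSums(counts) / (nT * pmax(n_sub, 1))
  }

  per_subunit <- do.call(rbind, lapply(subs, function(s) {
    nz <- which(counts[, s] > 0)
    if (length(nz) == 0) return(NULL)
    data.frame(residue_seq = all_res$residue_seq[nz],
               residue_name = all_res$residue_name[nz],
               subunit_id = s, frequency = freq[nz, s],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (is.null(per_subunit))
    per_subunit <- data.frame(residue_seq = integer(), residue_name = character(),
                              subunit_id = character(), frequency = numeric(),
                              stringsAsFactors = FALSE)
  nz <- which(combined_val > 0)
  combined <- data.frame(residue_seq = all_res$residue_seq[nz],
                         residue_name = all_res$residue_name[nz],
                         frequency = unname(combined_val[nz]),
                         stringsAsFactors = FALSE, row.names = NULL)
  structure(list(ligand_label = ligand$label, cutoff = cutoff, n_frames = nT,
                 combine_mode = combine_mode, per_subunit = per_subunit,
                 combined = combined),
            class = "contact_profile")
}

#' Query a contact frequency (0 for residues never in contact)
#'
#' @param profile a `contact_profile`.
#' @param residue_seq residue sequence number.
#' @param subunit optional subunit id; when `NULL` the subunit-combined
#'   frequency is returned.
#' @return a frequency in `[0, 1]`.
#' @export
contact_frequency <- function(profile, residue_seq, subunit = NULL) {
  if (is.null(subunit)) {
    hit <- profile$combined$residue_seq == residue_seq
    if (any(hit)) profile$combined$frequency[hit][1] else 0
  } else {
    hit <- profile$per_subunit$residue_seq == residue_seq &
      profile$per_subunit$subunit_id == subunit
    if (any(hit)) profile$per_subunit$frequency[hit][1] else 0
  }
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("Contact profile for '%s' (cutoff %.2f A, %d frames, %s):\n",
              x$ligand_label, x$cutoff, x$n_frames, x$combine_mode))
  print(head(x$combined[order(-x$combined$frequency), ], 10), row.names = FALSE)
  invisible(x)
}

#' Write/read a contact profile as TSV
#'
#' Columns: `residue_seq`, `residue_name`, `subunit`, `frequency`,
#' `combined`. One row per (residue, subunit) plus the combined value
#' repeated; header comment lines record the ligand label, cutoff, frame
#' count and combine mode so profiles are self-describing.
#'
#' @param profile a `contact_profile`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_contact_profile <- function(profile, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# ligand_label\t%s", profile$ligand_label), con)
  writeLines(sprintf("# cutoff\t%.6g", profile$cutoff), con)
  writeLines(sprintf("# n_frames\t%d", profile$n_frames), con)
  writeLines(sprintf("# combine_mode\t%s", profile$combine_mode), con)
  writeLines("residue_seq\tresidue_name\tsubunit\tfrequency\tcombined", con)
  ps <- profile$per_subunit
  comb <- setNames(profile$combined$frequency,
                   residue_key(profile$combined$residue_seq, profile$combined$residue_name))
  if (nrow(ps) > 0) {
    ck <- residue_key(ps$residue_seq, ps$residue_name)
    cv <- ifelse(ck %in% names(comb), comb[ck], 0)
    writeLines(sprintf("%d\t%s\t%s\t%.6f\t%.6f", ps$residue_seq, ps$residue_name,
                       ps$subunit_id, ps$frequency, cv), con)
  }
  # combined-only rows for residues present in combined but not per-subunit
  only <- setdiff(names(comb), residue_key(ps$residue_seq, ps$residue_name))
  if (length(only) > 0) {
    sel <- residue_key(profile$combined$residue_seq, profile$combined$residue_name) %in% only
    writeLines(sprintf("%d\t%s\t*\tNA\t%.6f", profile$combined$residue_seq[sel],
                       profile$combined$residue_name[sel],
                       profile$combined$frequency[sel]), con)
  }
  invisible(path)
}

#' @rdname write_contact_profile
#' @export
read_contact_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  meta <- do.call(rbind, strsplit(sub("^# ", "", hdr), "\t"))
  meta <- setNames(meta[, 2], meta[, 1])
  body <- read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  ps <- body[body$subunit != "*", , drop = FALSE]
  per_subunit <- data.frame(residue_seq = as.integer(ps$residue_seq),
                            residue_name = ps$residue_name,
                            subunit_id = as.character(ps$subunit),
                            frequency = as.numeric(ps$frequency),
                            stringsAsFactors = FALSE)
  cb <- unique(body[, c("residue_seq", "residue_name", "combined")])
  combined <- data.frame(residue_seq = as.integer(cb$residue_seq),
                         residue_name = cb$residue_name,
                         frequency = as.numeric(cb$combined),
                         stringsAsFactors = FALSE)
  combined <- combined[combined$frequency > 0, , drop = FALSE]
  structure(list(ligand_label = unname(meta["ligand_label"]),
                 cutoff = as.numeric(meta["cutoff"]),
                 n_frames = as.integer(meta["n_frames"]),
                 combine_mode = unname(meta["combine_mode"]),
                 per_subunit = per_subunit, combined = combined),
            class = "contact_profile")
}

#' Classify differential ligand selectivity of contact residues
#'
#' Splits the union of residues seen in two contact profiles into four
#' classes at a frequency threshold: `selective_A` (combined frequency at or
#' above the threshold for A, below it for B), `selective_B` (the converse),
#' `shared` (both at or above) and `neither`. Also reports the cumulative
#' frequency (sum over the two ligands, maximum 2) per residue.
#'
#' @param profile_a,profile_b `contact_profile` objects computed with the
#'   same cutoff and combine mode.
#' @param threshold frequency threshold in (0, 1); default 0.5, i.e. contact
#'   in at least half of the frames.
#' @return an object of class `selectivity_report`: a residue table
#'   (`residues`: residue_seq, residue_name, freq_a, freq_b, cumulative,
#'   class) plus the four class membership tables and the labels/threshold.
#' @export
classify_selectivity <- function(profile_a, profile_b, threshold = 0.5) {
  if (!isTRUE(all.equal(profile_a$cutoff, profile_b$cutoff)))
    stop("profiles computed with different cutoffs (",
         profile_a$cutoff, " vs ", profile_b$cutoff, ")")
  if (profile_a$combine_mode != profile_b$combine_mode)
    stop("profiles computed with different combine modes")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  u <- unique(rbind(profile_a$combined[, c("residue_seq", "residue_name")],
                    profile_b$combined[, c("residue_seq", "residue_name")]))
  u <- u[order(u$residue_seq), , drop = FALSE]
  fa <- vapply(u$residue_seq, function(r) contact_frequency(profile_a, r), numeric(1))
  fb <- vapply(u$residue_seq, function(r) contact_frequency(profile_b, r), numeric(1))
  cls <- ifelse(fa >= threshold & fb < threshold, "selective_A",
                ifelse(fb >= threshold & fa < threshold, "selective_B",
                       ifelse(fa >= threshold & fb >= threshold, "shared", "neither")))
  residues <- data.frame(residue_seq = u$residue_seq, residue_name = u$residue_name,
                         freq_a = fa, freq_b = fb, cumulative = fa + fb,
                         class = cls, stringsAsFactors = FALSE, row.names = NULL)
  pick <- function(k) residues[residues$class == k,
                               c("residue_seq", "residue_name"), drop = FALSE]
  structure(list(label_a = profile_a$ligand_label, label_b = profile_b$ligand_label,
                 threshold = threshold, residues = residues,
                 selective_A = pick("selective_A"), selective_B = pick("selective_B"),
                 shared = pick("shared"), neither = pick("neither")),
            class = "selectivity_report")
}

#' @export
print.selectivity_report <- function(x, ...) {
  cat(sprintf("Selectivity of %s vs %s at threshold %.2f:\n", x$label_a,
              x$label_b, x$threshold))
  for (k in c("selective_A", "selective_B", "shared", "neither")) {
    r <- x[[k]]
    cat(sprintf("  %-11s (%2d): %s\n", k, nrow(r),
                paste(residue_key(r$residue_seq, r$residue_name), collapse = " ")))
  }
  invisible(x)
}

#' Residues in contact with both ligands
#'
#' Convenience view returning the `shared` class of
#' [classify_selectivity()]: the residues whose subunit-averaged contact
#' frequency reaches the threshold for both ligand species.
#'
#' @inheritParams classify_selectivity
#' @return data frame with columns `residue_seq`, `residue_name`.
#' @export
dual_ligand_shared_contacts <- function(profile_a, profile_b, threshold = 0.5) {
  if (profile_a$combine_mode != "subunit_mean" ||
      profile_b$combine_mode != "subunit_mean")
    stop("dual_ligand_shared_contacts requires combine_mode = subunit_mean")
  classify_selectivity(profile_a, profile_b, threshold)$shared
}

#' Write a selectivity report as TSV
#' @param report a `selectivity_report`.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_selectivity_report <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# ligand_a\t%s", report$label_a), con)
  writeLines(sprintf("# ligand_b\t%s", report$label_b), con)
  writeLines(sprintf("# threshold\t%.6g", report$threshold), con)
  writeLines("residue_seq\tresidue_name\tfreq_a\tfreq_b\tcumulative\tclass", con)
  r <- report$residues
  writeLines(sprintf("%d\t%s\t%.6f\t%.6f\t%.6f\t%s", r$residue_seq,
                     r$residue_name, r$freq_a, r$freq_b, r$cumulative, r$class), con)
  invisible(path)
}
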