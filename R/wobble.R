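# Wobble decoding: orphan codons (sense codons with no genomically encoded
# Watson-Crick anticodon), their assignment to closely related isoacceptors
# of the same isotype, and demand-weighted redistribution of wobbling
# isoacceptor abundance onto the codons they serve.

#' Default wobble pairing rules
#'
#' Maps the anticodon wobble base (position 34, the first base of the
#' anticodon written 5'->3') to the set of codon third-position bases it can
#' read: the Watson-Crick partner plus the classical wobble extensions
#' (G34 reads C and U; U34 reads A and G; A34 is deaminated to inosine and
#' reads U, C and A; C34 reads only G). Bases are written in the DNA
#' alphabet. A custom table must still let every anticodon read its
#' Watson-Crick codon.
#'
#' @param overrides optional named list partially overriding the defaults.
#' @return Named list wobble base -> character vector of codon third bases.
#' @export
wobble_rules <- function(overrides = NULL) {
  rules <- list(G = c("C", "T"), T = c("A", "G"), A = c("T", "C", "A"),
                C = "G")
  if (!is.null(overrides)) rules[names(overrides)] <- overrides
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (b in names(rules)) {
    if (!comp[[b]] %in% rules[[b]]) {
      stopf("wobble rule for %s34 must include its Watson-Crick partner %s",
            b, comp[[b]])
    }
  }
  rules
}

#' Find orphan codons
#'
#' Sense codons whose Watson-Crick anticodon is absent from the encoded
#' isoacceptor families.
#'
#' @param code a [load_genetic_code()] object.
#' @param encoded_families character vector of family ids
#'   (`Isotype-ANTICODON`) or bare anticodons.
#' @return Sorted character vector of orphan codons.
#' @export
find_orphan_codons <- function(code, encoded_families) {
  anticodons <- sub(".*-", "", encoded_families)
  sense_anti <- codon_to_anticodon(code$sense_codons)
  sort(code$sense_codons[!sense_anti %in% anticodons])
}

wobble_base <- function(anticodon) substr(anticodon, 1L, 1L)

#' Assign wobble decoders to orphan codons
#'
#' Each orphan codon is matched to an encoded isoacceptor family of the same
#' isotype whose anticodon differs from the orphan's Watson-Crick anticodon
#' only at the wobble position (34) and whose wobble base can read the
#' orphan's third codon base under `rules`. When several candidates qualify
#' the deterministic preference order G34 > A34 > U34 > C34 applies.
#' Orphans with no qualifying family are recorded as unmatchable and are
#' excluded from downstream corrected correlations.
#'
#' @param orphans orphan codons ([find_orphan_codons()]).
#' @param encoded_families encoded family ids (`Isotype-ANTICODON`).
#' @param rules a [wobble_rules()] table.
#' @param code a [load_genetic_code()] object.
#' @return An object of class `decoding_map`: list with `codon_to_family`
#'   (named map over all served codons), `family_to_codons` (list), and
#'   `unmatchable` (orphans left unserved).
#' @export
assign_wobble_decoders <- function(orphans, encoded_families,
                                   rules = wobble_rules(),
                                   code = load_genetic_code()) {
  enc <- data.frame(
    family_id = encoded_families,
    isotype = sub("-.*", "", encoded_families),
    anticodon = sub(".*-", "", encoded_families),
    stringsAsFactors = FALSE
  )
  # Watson-Crick assignments first: every encoded family serves its own codon
  wc_codon <- codon_to_anticodon(enc$anticodon)
  sense <- wc_codon %in% code$sense_codons
  codon_to_family <- stats::setNames(enc$family_id[sense], wc_codon[sense])

  pref <- c(G = 1, A = 2, T = 3, C = 4)
  unmatchable <- character(0)
  for (oc in orphans) {
    iso <- AA_THREE[unname(code$table[oc])]
    wc_anti <- codon_to_anticodon(oc)
    cand <- enc[enc$isotype == iso &
                  substr(enc$anticodon, 2, 3) == substr(wc_anti, 2, 3), ,
                drop = FALSE]
    third <- substr(oc, 3, 3)
    ok <- vapply(wobble_base(cand$anticodon),
                 function(b) third %in% (rules[[b]] %||% character(0)),
                 logical(1))
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) {
      unmatchable <- c(unmatchable, oc)
      next
    }
    best <- cand$family_id[order(pref[wobble_base(cand$anticodon)])][1]
    codon_to_family[[oc]] <- best
  }
  family_to_codons <- split(names(codon_to_family), unname(codon_to_family))
  structure(list(codon_to_family = codon_to_family,
                 family_to_codons = family_to_codons,
                 unmatchable = sort(unmatchable)),
            class = "decoding_map")
}

#' @export
print.decoding_map <- function(x, ...) {
  cat("decoding_map:", length(x$codon_to_family), "codons served by",
      length(x$family_to_codons), "families;",
      length(x$unmatchable), "unmatchable orphan(s)\n")
  invisible(x)
}

#' Redistribute isoacceptor abundance over the codons each family serves
#'
#' A family serving several codons splits its cumulative abundance between
#' them in proportion to the codons' demand:
#' `availability(c) = A_f * U_c / sum_{c' in C(f)} U_{c'}`. If every served
#' codon has zero demand the abundance is split equally. Total availability
#' equals total abundance of the mapped families (conservation).
#'
#' @param family_abundance anticodon-level [usage_profile()].
#' @param dmap a [assign_wobble_decoders()] decoding map.
#' @param codon_demand normalized codon-level [usage_profile()].
#' @return Named numeric vector: per-codon tRNA availability.
#' @export
redistribute_abundance <- function(family_abundance, dmap, codon_demand) {
  fams <- intersect(names(dmap$family_to_codons), names(family_abundance$values))
  avail <- numeric(0)
  for (f in fams) {
    served <- dmap$family_to_codons[[f]]
    if (length(served) == 0) stopf("family %s serves no codon", f)
    d <- codon_demand$values[served]
    d[is.na(d)] <- 0
    w <- if (sum(d) > 0) d / sum(d) else rep(1 / length(served), length(served))
    add <- family_abundance$values[[f]] * w
    names(add) <- served
    avail <- c(avail, add)
  }
  # codons are served by exactly one family, so no aggregation needed;
  # keep a stable order
  avail[order(names(avail))]
}

#' Wobble-corrected interface correlation
#'
#' Builds the orphan-codon decoding map for the encoded families present in
#' `anticodon_u`, redistributes family abundance onto served codons by
#' demand, and correlates codon demand with the per-codon availability.
#' With no orphan codons this equals [interface_correlation()] exactly.
#'
#' @param codon_u normalized codon-level [usage_profile()].
#' @param anticodon_u anticodon-level [usage_profile()].
#' @param rules a [wobble_rules()] table.
#' @param code a [load_genetic_code()] object.
#' @return list with `rho`, `p`, `n_pairs`, `orphans`, `unmatchable`.
#' @export
wobble_corrected_correlation <- function(codon_u, anticodon_u,
                                         rules = wobble_rules(),
                                         code = load_genetic_code()) {
  enc <- names(anticodon_u$values)
  orphans <- find_orphan_codons(code, enc)
  dmap <- assign_wobble_decoders(orphans, enc, rules, code)
  avail <- redistribute_abundance(anticodon_u, dmap, codon_u)
  codons <- intersect(names(codon_u$values), names(avail))
  if (length(codons) < 4) stopf("need >= 4 served codons, got %d", length(codons))
  ct <- suppressWarnings(
    stats::cor.test(unname(codon_u$values[codons]), unname(avail[codons]),
                    method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = length(codons),
       orphans = orphans, unmatchable = dmap$unmatchable)
}
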