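# Per-panel allele bookkeeping: alt copies, observed copies, missing fraction.
.panel_counts <- function(gm, ids) {
  dos <- dosages(gm)[, ids, drop = FALSE]
  list(ac = rowSums(dos, na.rm = TRUE),
       an = 2L * rowSums(!is.na(dos)),
       miss = rowMeans(is.na(dos)))
}

#' Find donor-diagnostic alleles
#'
#' Identifies sites carrying an allele that is present in the donor panel
#' (in at least `min_donor_carriers` donor samples) and essentially absent
#' from every exclusion panel (observed frequency `<= max_exclusion_freq`).
#' The diagnostic allele may be REF or ALT: a donor species can be fixed for
#' either with respect to the reference assembly, and the chosen allele is
#' recorded per site.  "Absence" is evaluated on observed allele copies only;
#' a site is ineligible when the donor or any exclusion panel exceeds
#' `max_missing_per_panel` missing genotypes, or when an exclusion panel has
#' no observed copies at all.
#'
#' @param gm a [genotype_matrix()].
#' @param panels a [panel_config()] with `donor` and at least one
#'   `exclusion_*` panel.
#' @param min_donor_carriers minimum number of donor samples carrying the
#'   candidate allele (default 1).
#' @param max_exclusion_freq maximum observed frequency of the candidate
#'   allele in every exclusion panel (default 0, strict absence).
#' @param max_missing_per_panel maximum missing-genotype fraction tolerated
#'   in the donor and each exclusion panel (default 1, no bound).
#' @return data frame of class `diagnostic_alleles` with columns `contig`,
#'   `pos` (0-based), `allele` ("ref"/"alt"), `base`, `donor_carriers`,
#'   `donor_freq` and one `freq_<panel>` column per exclusion panel.
#' @export
find_diagnostic_alleles <- function(gm, panels, min_donor_carriers = 1,
                                    max_exclusion_freq = 0,
                                    max_missing_per_panel = 1) {
  validate_panels(panels, gm, require = c("donor", "exclusion"))
  stopifnot(.is_count(min_donor_carriers), min_donor_carriers >= 1,
            .is_prob(max_exclusion_freq), .is_prob(max_missing_per_panel))
  ex <- exclusion_panels(panels)
  don <- .panel_counts(gm, panels$donor)
  dos_d <- dosages(gm)[, panels$donor, drop = FALSE]
  carriers_alt <- rowSums(dos_d >= 1L, na.rm = TRUE)
  carriers_ref <- rowSums(dos_d <= 1L, na.rm = TRUE)

  exc <- lapply(ex, function(p) .panel_counts(gm, panels[[p]]))
  eligible <- don$miss <= max_missing_per_panel
  for (e in exc) eligible <- eligible & e$miss <= max_missing_per_panel & e$an > 0L
  if (!any(eligible))
    warning("no site eligible under the per-panel missingness bound",
            call. = FALSE)

  ok_alt <- eligible & don$an > 0L & carriers_alt >= min_donor_carriers
  ok_ref <- eligible & don$an > 0L & carriers_ref >= min_donor_carriers
  for (e in exc) {
    f_alt <- ifelse(e$an > 0L, e$ac / e$an, NA_real_)
    ok_alt <- ok_alt & f_alt <= max_exclusion_freq
    ok_ref <- ok_ref & (1 - f_alt) <= max_exclusion_freq
  }
  ok_alt[is.na(ok_alt)] <- FALSE; ok_ref[is.na(ok_ref)] <- FALSE
  # a site can in principle qualify through both alleles (only when
  # max_exclusion_freq is permissive); keep the allele with more donor
  # carriers, alt on ties
  both <- ok_alt & ok_ref
  use_ref <- ok_ref & (!ok_alt | (both & carriers_ref > carriers_alt))
  use_alt <- ok_alt & !use_ref
  idx <- which(use_alt | use_ref)
  is_alt <- use_alt[idx]
  out <- data.frame(
    contig = gm$contig[idx], pos = gm$pos[idx],
    allele = ifelse(is_alt, "alt", "ref"),
    base = ifelse(is_alt, gm$alt[idx], gm$ref[idx]),
    donor_carriers = ifelse(is_alt, carriers_alt[idx], carriers_ref[idx]),
    donor_freq = ifelse(is_alt, don$ac[idx] / don$an[idx],
                        1 - don$ac[idx] / don$an[idx]),
    stringsAsFactors = FALSE)
  for (i in seq_along(ex)) {
    f_alt <- ifelse(exc[[i]]$an > 0L, exc[[i]]$ac / exc[[i]]$an, NA_real_)[idx]
    out[[paste0("freq_", ex[i])]] <- ifelse(is_alt, f_alt, 1 - f_alt)
  }
  class(out) <- c("diagnostic_alleles", class(out))
  out
}

#' Write / read diagnostic-allele sets as TSV
#' @param das a `diagnostic_alleles` data frame.
#' @param path file path.
#' @export
write_diagnostics <- function(das, path) {
  utils::write.table(das, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagnostics
#' @export
read_diagnostics <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  class(d) <- c("diagnostic_alleles", class(d))
  d
}

#' Panel presence partition (Venn cells)
#'
#' A site is "present" in a panel when at least one non-missing copy of the
#' alt allele is observed there.  Counts sites by their presence pattern
#' across panels (Venn cells) and reports per-panel totals and
#' private-site counts.
#'
#' @param gm a [genotype_matrix()].
#' @param panels a [panel_config()] (or plain named list of sample ids);
#'   at least two panels.
#' @return list with `cells` (data frame: one row per non-empty presence
#'   pattern, logical column per panel, plus `count`), `per_panel`
#'   (present/private counts per panel) and `total` (sites present in at
#'   least one panel).
#' @export
panel_partition <- function(gm, panels) {
  if (length(panels) < 2L) .stopf("panel_partition() needs >= 2 panels")
  if (is.null(names(panels))) .stopf("panels must be named")
  unknown <- setdiff(unlist(panels, use.names = FALSE), gm$samples)
  if (length(unknown))
    .stopf("panel sample(s) not present in the callset: %s",
           paste(unknown, collapse = ", "))
  pres <- vapply(panels, function(ids)
    .panel_counts(gm, ids)$ac >= 1L, logical(n_sites(gm)))
  pres <- matrix(pres, ncol = length(panels),
                 dimnames = list(NULL, names(panels)))
  any_pres <- rowSums(pres) > 0L
  pat <- apply(pres[any_pres, , drop = FALSE], 1L,
               function(r) paste(as.integer(r), collapse = ""))
  tab <- table(pat)
  cells <- do.call(rbind, lapply(names(tab), function(p)
    strsplit(p, "")[[1L]] == "1"))
  cells <- as.data.frame(cells)
  names(cells) <- names(panels)
  cells$count <- as.integer(tab)
  private <- vapply(seq_along(panels), function(j) {
    sum(cells$count[cells[[j]] & rowSums(cells[, seq_along(panels),
                                               drop = FALSE]) == 1L])
  }, integer(1L))
  per_panel <- data.frame(panel = names(panels),
                          present = colSums(pres),
                          private = private, row.names = NULL)
  list(cells = cells, per_panel = per_panel, total = sum(any_pres))
}
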