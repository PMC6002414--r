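#' Panel configuration
#'
#' Maps samples to analysis roles.  Recognised roles are `donor`,
#' `recipient`, `outgroup` and any number of exclusion panels named
#' `exclusion_1`, `exclusion_2`, ...  Roles must be disjoint.
#'
#' @param ... named character vectors of sample ids, one per role.
#' @return a named list of class `panel_config`.
#' @export
panel_config <- function(...) {
  panels <- list(...)
  if (length(panels) == 1L && is.list(panels[[1L]]) && is.null(names(panels)))
    panels <- panels[[1L]]
  nms <- names(panels)
  if (is.null(nms) || any(!nzchar(nms))) .stopf("all panels must be named")
  ok <- grepl("^(donor|recipient|outgroup|exclusion_[0-9]+)$", nms)
  if (any(!ok)) .stopf("unknown panel role(s): %s", paste(nms[!ok], collapse = ", "))
  all_ids <- unlist(panels, use.names = FALSE)
  if (anyDuplicated(all_ids))
    .stopf("sample(s) assigned to more than one role: %s",
           paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  structure(lapply(panels, as.character), class = "panel_config")
}

#' Read a panel configuration from TSV
#'
#' @param path headered TSV with columns `sample_id` and `role`.
#' @return a [panel_config()].
#' @export
read_panels <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "role") %in% names(d)))
  panel_config(split(d$sample_id, d$role))
}

#' Write a panel configuration to TSV
#' @param panels a [panel_config()].
#' @param path output path.
#' @export
write_panels <- function(panels, path) {
  d <- data.frame(sample_id = unlist(panels, use.names = FALSE),
                  role = rep(names(panels), lengths(panels)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Names of the exclusion panels in a configuration
#' @param panels a [panel_config()].
#' @export
exclusion_panels <- function(panels) {
  grep("^exclusion_", names(panels), value = TRUE)
}

#' Validate panels against a genotype matrix
#'
#' Checks that every panel sample exists in the callset (fatal with the
#' offending names otherwise) and that the roles needed by the requested
#' analysis are present: a diagnostic scan needs `donor`, `recipient` and at
#' least one exclusion panel; the D statistic additionally needs `outgroup`.
#'
#' @param panels a [panel_config()].
#' @param gm a [genotype_matrix()] (or a character vector of sample ids).
#' @param require character vector of required roles; `"exclusion"` means at
#'   least one exclusion panel.
#' @return `panels`, invisibly.
#' @export
validate_panels <- function(panels, gm, require = character()) {
  samples <- if (inherits(gm, "genotype_matrix")) gm$samples else gm
  unknown <- setdiff(unlist(panels, use.names = FALSE), samples)
  if (length(unknown))
    .stopf("panel sample(s) not present in the callset: %s",
           paste(unknown, collapse = ", "))
  for (r in require) {
    if (r == "exclusion") {
      if (length(exclusion_panels(panels)) == 0L)
        .stopf("at least one exclusion panel is required")
    } else if (is.null(panels[[r]]) || length(panels[[r]]) == 0L) {
      .stopf("panel role '%s' is required but empty or absent", r)
    }
  }
  invisible(panels)
}
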