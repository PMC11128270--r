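#' Frequency of occurrence of prey species
#'
#' FOO(species, group) = proportion of identifiable samples in the group in
#' which the species occurs at least once (presence-based: duplicating an
#' item within a sample changes nothing). Samples with no identifiable
#' remains are excluded before anything is counted. Groups with zero
#' identifiable samples are omitted with a warning.
#'
#' @param samples A `diet_samples` data.frame (see [read_diet_csv()]).
#' @param group_by Grouping columns, default `c("sex", "year")`; use
#'   `character(0)` for a single pooled group.
#' @return data.frame: grouping columns, `species`, `n_samples`
#'   (identifiable samples in group), `n_occurrences`, `foo`.
#' @export
foo_table <- function(samples, group_by = c("sex", "year")) {
  id_samples <- unique(samples[samples$identifiable,
                               c("sample_id", group_by), drop = FALSE])
  all_groups <- unique(samples[, group_by, drop = FALSE])
  species <- sort(unique(samples$species[samples$identifiable & samples$species != ""]))
  key <- function(df) {
    if (length(group_by) == 0) rep("all", nrow(df))
    else do.call(paste, c(df[group_by], sep = "\r"))
  }
  gk_all <- unique(key(all_groups))
  gk_id <- key(id_samples)
  empty <- setdiff(gk_all, unique(gk_id))
  if (length(empty)) {
    warning(sprintf("%d group(s) with no identifiable samples omitted",
                    length(empty)))
  }
  items <- samples[samples$identifiable & samples$species != "", , drop = FALSE]
  rows <- list()
  for (g in unique(gk_id)) {
    sids <- id_samples$sample_id[gk_id == g]
    n <- length(sids)
    sub <- items[items$sample_id %in% sids, , drop = FALSE]
    meta <- id_samples[gk_id == g, group_by, drop = FALSE][1, , drop = FALSE]
    for (sp in species) {
      occ <- length(unique(sub$sample_id[sub$species == sp]))
      rows[[length(rows) + 1]] <- cbind(
        meta, data.frame(species = sp, n_samples = n, n_occurrences = occ,
                         foo = occ / n), row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean numerical abundance of prey species
#'
#' Mean, over all identifiable samples in the group, of the per-sample total
#' count of the species; samples lacking the species contribute 0. (The
#' alternative denominator — only samples containing the species — is
#' available via `present_only = TRUE`.)
#'
#' @inheritParams foo_table
#' @param present_only Divide by samples containing the species instead of
#'   all identifiable samples, default FALSE.
#' @return data.frame: grouping columns, `species`, `n_samples`,
#'   `mean_count`.
#' @export
numerical_abundance <- function(samples, group_by = c("sex", "year"),
                                present_only = FALSE) {
  foo <- foo_table(samples, group_by)
  items <- samples[samples$identifiable & samples$species != "", , drop = FALSE]
  key <- function(df) {
    if (length(group_by) == 0) rep("all", nrow(df))
    else do.call(paste, c(df[group_by], sep = "\r"))
  }
  fk <- key(foo); ik <- key(items)
  foo$mean_count <- vapply(seq_len(nrow(foo)), function(r) {
    sel <- ik == fk[r] & items$species == foo$species[r]
    tot <- sum(items$count[sel])
    den <- if (present_only) max(foo$n_occurrences[r], 1) else foo$n_samples[r]
    tot / den
  }, 0)
  foo$foo <- NULL
  foo$n_occurrences <- NULL
  foo
}

#' Whole-prey length summary
#'
#' Mean and standard error of recorded lengths of whole prey items (rows with
#' a non-missing `length_cm`), all species combined, per group. Groups with a
#' single measured item get `se = NA` and a flag; groups with none are
#' omitted with a warning.
#'
#' @inheritParams foo_table
#' @param group_by Grouping columns, default `"sex"`.
#' @return data.frame: grouping columns, `n_items`, `mean_cm`, `se_cm`,
#'   `se_undefined`.
#' @export
prey_length_summary <- function(samples, group_by = "sex") {
  whole <- samples[samples$identifiable & !is.na(samples$length_cm), , drop = FALSE]
  key <- function(df) {
    if (length(group_by) == 0) rep("all", nrow(df))
    else do.call(paste, c(df[group_by], sep = "\r"))
  }
  all_k <- unique(key(unique(samples[, group_by, drop = FALSE])))
  wk <- key(whole)
  if (length(setdiff(all_k, unique(wk)))) {
    warning("group(s) with no whole prey items omitted")
  }
  rows <- lapply(unique(wk), function(g) {
    len <- rep(whole$length_cm[wk == g], whole$count[wk == g])
    meta <- whole[wk == g, group_by, drop = FALSE][1, , drop = FALSE]
    n <- length(len)
    cbind(meta, data.frame(
      n_items = n, mean_cm = mean(len),
      se_cm = if (n > 1) stats::sd(len) / sqrt(n) else NA_real_,
      se_undefined = n <= 1), row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
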