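#' Mean-normalize TMT reporter channels
#'
#' Each reporter channel is summed across all quantified proteins and scaled
#' by (mean of all channel sums) / (its own sum), the equal-loading
#' assumption used in isobaric-label post-processing. After normalization
#' every channel sums to the pre-normalization mean; within-channel protein
#' ratios are untouched and the operation is idempotent.
#'
#' @param intensities Tibble whose first column identifies the protein and
#'   whose remaining numeric columns are reporter channels (non-negative).
#' @return The normalized tibble (same shape).
#' @examples
#' m <- tibble::tibble(protein = c("P1", "P2"),
#'                     a = c(40, 60), b = c(100, 200))
#' normalize_channels(m)   # both channels then sum to 200
#' @export
normalize_channels <- function(intensities) {
  chans <- channel_columns(intensities)
  sums <- vapply(intensities[chans], sum, numeric(1))
  if (any(sums <= 0)) {
    abort(sprintf("channel with non-positive sum: %s",
                  paste(chans[sums <= 0], collapse = ", ")))
  }
  target <- mean(sums)
  for (ch in chans) {
    intensities[[ch]] <- intensities[[ch]] * (target / sum(intensities[[ch]]))
  }
  intensities
}

channel_columns <- function(intensities) {
  num <- vapply(intensities, is.numeric, logical(1))
  chans <- names(intensities)[num]
  if (length(chans) < 2) abort("need at least two numeric channel columns")
  bad <- vapply(intensities[chans],
                function(x) any(!is.finite(x)) || any(x < 0), logical(1))
  if (any(bad)) {
    abort(sprintf("non-finite or negative intensities in: %s",
                  paste(chans[bad], collapse = ", ")))
  }
  chans
}

#' Build a channel-to-group design
#'
#' @param channel Channel column names.
#' @param group Group label per channel (e.g. `"minus_tet"`, `"plus_tet"`;
#'   other labels such as `"unused"` are carried but ignored by testing).
#' @return A design tibble.
#' @export
channel_design <- function(channel, group) {
  stopifnot(length(channel) == length(group))
  tibble(channel = channel, group = group)
}

#' Differential protein abundance between two channel groups
#'
#' Per protein: `log2fc = log2(mean(test) / mean(reference))` on the raw
#' (normalized) intensity scale, and a two-sided Welch t-test on log2
#' intensities (`var_equal = TRUE` switches to the pooled-variance form).
#' The sign convention makes proteins that *drop* upon induction of the
#' depletion construct (+Tet) negative. Proteins with a zero group mean or
#' degenerate within-group variance in both groups are flagged and excluded
#' from thresholding.
#'
#' @param intensities Normalized intensity tibble (see
#'   [normalize_channels()]).
#' @param design A [channel_design()] mapping channels to groups.
#' @param reference,test Group labels for the denominator (control, −Tet)
#'   and numerator (depleted, +Tet) of the fold change.
#' @param var_equal Use the pooled-variance t-test? Default `FALSE` (Welch).
#' @return A `protein_stats` tibble `(protein, log2fc, p_value, flag)`;
#'   `flag` is `"ok"`, `"zero_group_mean"` or `"constant"`.
#' @export
differential_abundance <- function(intensities, design,
                                   reference = "minus_tet",
                                   test = "plus_tet", var_equal = FALSE) {
  chans <- channel_columns(intensities)
  ref_ch <- design$channel[design$group == reference]
  test_ch <- design$channel[design$group == test]
  stopifnot(length(ref_ch) >= 2, length(test_ch) >= 2,
            all(c(ref_ch, test_ch) %in% chans))
  ref_m <- as.matrix(intensities[ref_ch])
  test_m <- as.matrix(intensities[test_ch])
  n <- nrow(intensities)
  log2fc <- rep(NA_real_, n); pval <- rep(NA_real_, n)
  flag <- rep("ok", n)
  for (i in seq_len(n)) {
    mr <- mean(ref_m[i, ]); mt <- mean(test_m[i, ])
    if (mr <= 0 || mt <= 0) {
      flag[i] <- "zero_group_mean"
      next
    }
    log2fc[i] <- log2(mt / mr)
    lr <- log2(ref_m[i, ]); lt <- log2(test_m[i, ])
    if (sd(lr) == 0 && sd(lt) == 0) {
      flag[i] <- "constant"
      pval[i] <- 1
      next
    }
    pval[i] <- tryCatch(
      t.test(lt, lr, var.equal = var_equal)$p.value,
      error = function(e) NA_real_
    )
  }
  out <- tibble(protein = intensities[[1]], log2fc = log2fc,
                p_value = pval, flag = flag)
  class(out) <- c("protein_stats", class(out))
  out
}

#' Call significantly changed proteins
#'
#' The published screening thresholds: `p < p_max` and `|log2fc| >= lfc_cut`
#' (the fold-change boundary is inclusive — a protein at exactly -0.5
#' counts as downregulated). Flagged proteins are never called.
#'
#' @param stats A `protein_stats` tibble from [differential_abundance()],
#'   or any tibble with `protein`, `log2fc`, `p_value`.
#' @param p_max Significance threshold (default 0.05, uncorrected, matching
#'   the published analysis).
#' @param lfc_cut Absolute log2 fold-change threshold (default 0.5).
#' @param p_adjust Multiple-testing correction applied before gating
#'   (a [stats::p.adjust()] method; default `"none"`, matching the
#'   published raw-p threshold; e.g. `"BH"` for an FDR variant).
#' @return `stats` with a `call` column (`"down"`, `"up"`, `"ns"`), plus
#'   attributes `down` and `up` holding the id sets.
#' @export
apply_thresholds <- function(stats, p_max = 0.05, lfc_cut = 0.5,
                             p_adjust = "none") {
  flag_ok <- if ("flag" %in% names(stats)) stats$flag == "ok" else
    rep(TRUE, nrow(stats))
  p_gate <- p.adjust(stats$p_value, method = p_adjust)
  usable <- flag_ok & is.finite(stats$log2fc) & is.finite(stats$p_value)
  call <- rep("ns", nrow(stats))
  call[usable & p_gate < p_max & stats$log2fc <= -lfc_cut] <- "down"
  call[usable & p_gate < p_max & stats$log2fc >= lfc_cut] <- "up"
  stats$call <- call
  attr(stats, "down") <- stats$protein[call == "down"]
  attr(stats, "up") <- stats$protein[call == "up"]
  stats
}

#' Overlap differential results with a target list
#'
#' Intersects the significant sets with a list of known transcriptional
#' targets (gene symbols, case-insensitive) and, when a second study's
#' differential table is given, classifies the common significant genes into
#' the four concordance groups: I = up in both studies, II = down here / up
#' there, III = up here / down there, IV = down in both.
#'
#' @param stats A thresholded `protein_stats` (see [apply_thresholds()])
#'   with a `call` column.
#' @param targets Character vector of target gene symbols.
#' @param second Optional second differential table with `protein` and
#'   `call` columns (same conventions).
#' @return An `overlap_report`: counts and id lists for targets present,
#'   significantly down, significantly up, and groups I-IV.
#' @export
overlap_with_targets <- function(stats, targets, second = NULL) {
  if (anyDuplicated(toupper(targets))) {
    warn("duplicate target ids; de-duplicating")
  }
  targets <- unique(toupper(targets))
  stats <- mutate(stats, .sym = toupper(.data$protein))
  if (anyDuplicated(stats$.sym)) {
    warn("duplicate protein ids in stats; keeping first occurrence")
    stats <- stats[!duplicated(stats$.sym), , drop = FALSE]
  }
  present <- dplyr::filter(stats, .data$.sym %in% targets)
  down <- present$protein[present$call == "down"]
  up <- present$protein[present$call == "up"]
  groups <- NULL
  if (!is.null(second)) {
    second <- mutate(second, .sym = toupper(.data$protein))
    second <- second[!duplicated(second$.sym), , drop = FALSE]
    common <- inner_join(
      select(stats, "protein", ".sym", here = "call"),
      select(second, ".sym", there = "call"),
      by = ".sym"
    )
    common <- dplyr::filter(common, .data$here != "ns" & .data$there != "ns")
    groups <- list(
      I = common$protein[common$here == "up" & common$there == "up"],
      II = common$protein[common$here == "down" & common$there == "up"],
      III = common$protein[common$here == "up" & common$there == "down"],
      IV = common$protein[common$here == "down" & common$there == "down"]
    )
  }
  structure(
    list(n_targets = length(targets), n_present = nrow(present),
         present = present$protein, down = down, up = up,
         n_down = length(down), n_up = length(up), groups = groups),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report>\n")
  cat(sprintf("  targets: %d, present in data: %d\n", x$n_targets,
              x$n_present))
  cat(sprintf("  significantly down: %d, up: %d\n", x$n_down, x$n_up))
  if (!is.null(x$groups)) {
    cat(sprintf("  groups I/II/III/IV: %d/%d/%d/%d\n",
                length(x$groups$I), length(x$groups$II),
                length(x$groups$III), length(x$groups$IV)))
  }
  invisible(x)
}

#' @rdname overlap_with_targets
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @export
tidy.overlap_report <- function(x, ...) {
  base <- tibble(set = c("present", "down", "up"),
                 n = c(x$n_present, x$n_down, x$n_up))
  if (!is.null(x$groups)) {
    base <- bind_rows(base, tibble(set = paste0("group_", names(x$groups)),
                                   n = lengths(x$groups)))
  }
  base
}

#' Volcano plot of differential abundance
#'
#' @param stats A thresholded `protein_stats`.
#' @param p_max,lfc_cut Thresholds to draw.
#' @return A ggplot object.
#' @export
plot_volcano <- function(stats, p_max = 0.05, lfc_cut = 0.5) {
  df <- dplyr::filter(stats, is.finite(.data$log2fc) &
                        is.finite(.data$p_value))
  ggplot(df, aes(x = .data$log2fc, y = -log10(.data$p_value),
                 colour = .data$call)) +
    geom_point(size = 0.7, alpha = 0.7) +
    geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = 2) +
    geom_hline(yintercept = -log10(p_max), linetype = 2) +
    labs(x = "log2 fold change (+Tet / -Tet)", y = "-log10 p") +
    theme_minimal()
}

#' Packaged target tables
#'
#' The two published lists of characterized EWS-FLI1 downstream targets
#' whose protein abundance responds to deubiquitinase depletion: 33
#' downregulated and 6 upregulated genes with their log2 fold changes
#' (sign convention: negative = lower upon depletion).
#'
#' @param which `"down"` (33 genes) or `"up"` (6 genes).
#' @return Tibble `(gene, protein_name, log2fc)`.
#' @export
target_table <- function(which = c("down", "up")) {
  which <- match.arg(which)
  f <- if (which == "down") "table1.csv" else "table2.csv"
  path <- system.file("extdata", f, package = "pocketscreen")
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Read an intensity matrix from CSV/TSV
#'
#' @param path File with a protein id column followed by channel columns.
#' @return Tibble.
#' @export
read_intensity_matrix <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  as_tibble(read.csv(path, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE))
}
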