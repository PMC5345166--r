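#' Summarize rearrangement events across a cohort
#'
#' Collapses per-individual duplication/deletion calls to independent
#' events (one event per family per event class) and reports, per class and
#' overall, how many events include the derived locus (paralog B), with
#' percentages rounded to the nearest integer.
#'
#' @param event_calls Data frame with columns `sample`, `class`
#'   (`"duplication"` or `"deletion"`), and logical `includes_locus_B`.
#' @param family_map Optional data frame `sample`, `family` grouping related
#'   carriers; unlisted samples are their own family.
#' @return A data frame of class `cohort_summary` with rows `duplication`,
#'   `deletion` and `overall`, columns `n_events`, `n_including_locus_B`,
#'   `percent_including`.
#' @examples
#' calls <- data.frame(
#'   sample = sprintf("s%02d", 1:45),
#'   class = rep(c("duplication", "deletion"), c(15, 30)),
#'   includes_locus_B = rep(c(TRUE, FALSE, TRUE, FALSE), c(13, 2, 28, 2)))
#' summarize_rearrangements(calls)
#' @export
summarize_rearrangements <- function(event_calls, family_map = NULL) {
  ev <- as.data.frame(event_calls)
  stopifnot(all(c("sample", "class", "includes_locus_B") %in% names(ev)))
  if (!all(ev$class %in% c("duplication", "deletion"))) {
    stop("class must be 'duplication' or 'deletion'", call. = FALSE)
  }
  if (!is.null(family_map)) {
    fm <- as.data.frame(family_map)
    ev$family <- fm$family[match(ev$sample, fm$sample)]
    ev$family[is.na(ev$family)] <- ev$sample[is.na(ev$family)]
  } else {
    ev$family <- ev$sample
  }
  key <- paste(ev$family, ev$class, sep = "\r")
  dedup <- lapply(split(ev, key), function(g) {
    if (length(unique(g$includes_locus_B)) > 1L) {
      warning("conflicting inclusion calls within family ", g$family[1],
              " (", g$class[1], "); using the majority", call. = FALSE)
    }
    g$includes_locus_B <- mean(g$includes_locus_B) >= 0.5
    g[1, , drop = FALSE]
  })
  dd <- do.call(rbind, dedup)
  row_for <- function(sub, label) {
    n <- nrow(sub)
    inc <- sum(sub$includes_locus_B)
    data.frame(class = label, n_events = n, n_including_locus_B = inc,
               percent_including = if (n > 0) round(100 * inc / n) else
                 NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row_for(dd[dd$class == "duplication", ], "duplication"),
    row_for(dd[dd$class == "deletion", ], "deletion"),
    row_for(dd, "overall")
  )
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Plot a per-target paralog-specific copy-number profile
#'
#' Scatter of per-target paralog-specific point estimates for one sample
#' (paralog A in red, paralog B in blue), with called event spans shaded.
#' Rendering to the same file from the same inputs is deterministic.
#'
#' @param estimates Data frame from [paralog_point_estimates()] restricted
#'   to one sample (columns `target_index`, `cnA_hat`, `cnB_hat`).
#' @param calls Optional call table from [call_cn()] (rows with
#'   `kind != "none"` are shaded).
#' @param file Optional output path; `.svg` and `.pdf` are supported. When
#'   `NULL` the ggplot object is returned unprinted.
#' @param title Plot title.
#' @return The ggplot object, invisibly when written to file.
#' @export
plot_paralog_profile <- function(estimates, calls = NULL, file = NULL,
                                 title = NULL) {
  est <- as.data.frame(estimates)
  long <- rbind(
    data.frame(target_index = est$target_index, cn = est$cnA_hat,
               paralog = "A"),
    data.frame(target_index = est$target_index, cn = est$cnB_hat,
               paralog = "B")
  )
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$target_index, y = .data$cn,
                                    colour = .data$paralog)) +
    ggplot2::scale_colour_manual(values = c(A = "#c0392b", B = "#2471a3")) +
    ggplot2::geom_hline(yintercept = 0:4, linewidth = 0.2,
                        colour = "grey85") +
    ggplot2::labs(x = "MIP target index", y = "paralog-specific copy number",
                  title = title) +
    ggplot2::coord_cartesian(ylim = c(-0.3, 4.5)) +
    ggplot2::theme_minimal()
  if (!is.null(calls)) {
    ev <- as.data.frame(calls)
    ev <- ev[ev$kind != "none", , drop = FALSE]
    if (nrow(ev) > 0) {
      p <- p + ggplot2::geom_rect(
        data = ev,
        ggplot2::aes(xmin = .data$start_target - 0.5,
                     xmax = .data$end_target - 0.5),
        ymin = -Inf, ymax = Inf, fill = "grey70", alpha = 0.25,
        inherit.aes = FALSE)
    }
  }
  p <- p + ggplot2::geom_point(size = 1.2)
  if (is.null(file)) return(p)
  ext <- tolower(tools::file_ext(file))
  if (ext == "svg") {
    grDevices::svg(file, width = 8, height = 3)
  } else if (ext == "pdf") {
    grDevices::pdf(file, width = 8, height = 3)
  } else {
    stop("unsupported plot format: ", ext, call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  print(p)
  invisible(p)
}
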