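#' Density-strip figure of parameter estimates across replicates
#'
#' One panel per scored parameter; within a panel, every replicate
#' contributes one curve per model: frequentist fits are drawn as
#' Normal(estimate, SE) densities, Bayesian fits as kernel densities of
#' their posterior draws. A dashed vertical line marks the true value.
#' The visual signature of the collider problem is immediate: in case 2
#' the linear-model body-size densities pile up around 0 while the SEM
#' densities straddle the dashed line at 1.
#'
#' @param x a `brain_experiment` run with `keep_draws = TRUE`, or a
#'   directory written by [run_experiment()] containing `replicates.csv`
#'   and a `draws/` subdirectory for the Bayesian models.
#' @param parameters which parameters to show (default: all scored).
#' @param file output path; its extension (or `format`) selects the
#'   device. If NULL the ggplot object is returned unrendered.
#' @param format `"png"`, `"pdf"` or `"svg"`; used when `file` has no
#'   recognized extension.
#' @param width,height device size in inches.
#' @return the ggplot object (invisibly when written to `file`).
#' @export
render_estimates_figure <- function(x, parameters = NULL, file = NULL,
                                    format = c("png", "pdf", "svg"),
                                    width = 8, height = 4.5) {
  format <- match.arg(format)
  if (is.character(x) && length(x) == 1L) x <- read_experiment_dir(x)
  stopifnot(inherits(x, "brain_experiment"))
  reps <- x$replicates
  if (is.null(reps) || nrow(reps) == 0L)
    stop("experiment has no replicate results; nothing to plot",
         call. = FALSE)
  if (!is.null(parameters)) {
    reps <- reps[reps$parameter %in% parameters, , drop = FALSE]
    if (nrow(reps) == 0L)
      stop("no replicate rows for parameter(s): ",
           paste(parameters, collapse = ", "), call. = FALSE)
  }

  bayes_models <- intersect(unique(reps$model), c("bayes_linear", "sem"))
  if (length(bayes_models)) {
    need <- unique(with(reps[reps$model %in% bayes_models, ],
                        paste(case_id, model, replicate_index, sep = "_")))
    have <- names(x$draws)
    missing <- setdiff(need, have)
    if (length(missing))
      stop("posterior draws missing for: ",
           paste(utils::head(missing, 8), collapse = ", "),
           if (length(missing) > 8) " ..." else "",
           " (run the experiment with keep_draws = TRUE)", call. = FALSE)
  }

  curves <- vector("list", nrow(reps))
  for (i in seq_len(nrow(reps))) {
    r <- reps[i, ]
    if (r$model == "linear") {
      grid <- seq(r$point_estimate - 4 * r$uncertainty,
                  r$point_estimate + 4 * r$uncertainty, length.out = 101)
      dens <- stats::dnorm(grid, r$point_estimate, r$uncertainty)
    } else {
      key <- paste(r$case_id, r$model, r$replicate_index, sep = "_")
      dr <- x$draws[[key]][, r$parameter]
      kd <- stats::density(dr)
      grid <- kd$x
      dens <- kd$y
    }
    curves[[i]] <- data.frame(case_id = r$case_id, model = r$model,
                              replicate_index = r$replicate_index,
                              parameter = r$parameter,
                              value = grid, dens = dens)
  }
  curves <- do.call(rbind, curves)
  truth_df <- unique(reps[, c("case_id", "parameter", "truth")])

  multi_case <- length(unique(reps$case_id)) > 1L
  p <- ggplot2::ggplot(curves,
         ggplot2::aes(x = value, y = dens,
                      group = interaction(model, replicate_index),
                      colour = model)) +
    ggplot2::geom_line(alpha = 0.45, linewidth = 0.3) +
    ggplot2::geom_vline(data = truth_df,
                        ggplot2::aes(xintercept = truth),
                        linetype = "dashed", colour = "grey40") +
    (if (multi_case)
       ggplot2::facet_grid(case_id ~ parameter, scales = "free")
     else
       ggplot2::facet_wrap(~parameter, scales = "free")) +
    ggplot2::labs(x = "parameter estimate", y = "density",
                  colour = "model") +
    ggplot2::theme_minimal()

  if (is.null(file)) return(p)
  ext <- tolower(tools::file_ext(file))
  if (!ext %in% c("png", "pdf", "svg")) {
    file <- paste0(file, ".", format)
    ext <- format
  }
  dev <- switch(ext, png = grDevices::png, pdf = grDevices::pdf,
                svg = grDevices::svg)
  if (ext == "png")
    ggplot2::ggsave(file, p, width = width, height = height, dpi = 150,
                    device = dev, units = "in", bg = "white")
  else
    ggplot2::ggsave(file, p, width = width, height = height, device = dev,
                    units = "in", bg = "white")
  invisible(p)
}

# reconstruct a minimal brain_experiment from a persisted run directory
read_experiment_dir <- function(dir) {
  repf <- file.path(dir, "replicates.csv")
  if (!file.exists(repf))
    stop("missing file: ", repf, call. = FALSE)
  reps <- utils::read.csv(repf)
  draws <- list()
  dd <- file.path(dir, "draws")
  if (dir.exists(dd)) {
    for (f in list.files(dd, pattern = "\\.csv$", full.names = TRUE)) {
      key <- sub("\\.csv$", "", basename(f))
      draws[[key]] <- as.matrix(utils::read.csv(f))
    }
  }
  structure(list(replicates = reps,
                 summary = if (file.exists(file.path(dir, "summary.csv")))
                   utils::read.csv(file.path(dir, "summary.csv")) else NULL,
                 failures = NULL, log = NULL, scenario = NULL,
                 datasets = NULL, draws = draws),
            class = "brain_experiment")
}
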