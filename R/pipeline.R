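#' Configure a GPSM evaluation experiment
#'
#' Bundles every choice of a filter–split–train–generate–score experiment
#' into one validated object, with an explicit seed per stochastic stage
#' so reruns byte-reproduce the report.
#'
#' @param msa Source alignment: an [encoded_msa] or a FASTA/Stockholm
#'   path.
#' @param filter Apply identity filtering before the split?
#' @param threshold Identity threshold for filtering/splitting.
#' @param train_size,ref_size Half sizes (default: equal split of the
#'   survivors, odd one to training).
#' @param models Character subset of `c("potts", "independent")`.
#' @param orders,n_sets,top_k r20 settings (see [r20()]).
#' @param eval_size Evaluation MSA size; default matches the reference
#'   size (the standard control — training, reference, and evaluation
#'   MSAs carry the same number of sequences).
#' @param potts_args List of extra arguments for [fit_potts()].
#' @param bootstrap Bootstrap replicates for CIs on per-order means.
#' @param seed Base seed; stage seeds default to `seed + 0..4`
#'   (filter/split, fit, generate, metric, bootstrap) and can be
#'   overridden via `seeds`.
#' @param seeds Optional named list overriding individual stage seeds.
#' @param out_dir Optional directory: writes per-arm FASTA MSAs and a
#'   JSON report.
#' @return A validated list of class `"experiment_config"`.
#' @export
experiment_config <- function(msa, filter = TRUE, threshold = 0.5,
                              train_size = NULL, ref_size = NULL,
                              models = c("potts", "independent"),
                              orders = 2:5, n_sets = 1000L, top_k = 20L,
                              eval_size = NULL, potts_args = list(),
                              bootstrap = 200L, seed = 1L, seeds = NULL,
                              out_dir = NULL) {
  models <- match.arg(models, c("potts", "independent"),
                      several.ok = TRUE)
  seed <- .check_count(seed, "seed", min = 0L)
  stage_seeds <- list(split = seed, fit = seed + 1L, generate = seed + 2L,
                      metric = seed + 3L, bootstrap = seed + 4L)
  if (!is.null(seeds)) {
    stopifnot(all(names(seeds) %in% names(stage_seeds)))
    stage_seeds[names(seeds)] <- seeds
  }
  structure(list(msa = msa, filter = isTRUE(filter), threshold = threshold,
                 train_size = train_size, ref_size = ref_size,
                 models = models, orders = orders,
                 n_sets = .check_count(n_sets, "n_sets"),
                 top_k = .check_count(top_k, "top_k"),
                 eval_size = eval_size, potts_args = potts_args,
                 bootstrap = .check_count(bootstrap, "bootstrap"),
                 seeds = stage_seeds, out_dir = out_dir),
            class = "experiment_config")
}

#' Run a GPSM evaluation experiment
#'
#' Executes the full design: (optionally) identity-filter and
#' phylogeny-aware-split the source MSA into training and reference
#' halves, fit the requested models on the training half, generate an
#' evaluation MSA per model sized to the reference, and score every arm
#' with r20 and cc-r20 against the reference over *shared* position sets,
#' alongside the finite-sampling null (training vs reference). Each stage
#' uses its configured seed, so rerunning the config reproduces the
#' report.
#'
#' @param config An [experiment_config()].
#' @return Object of class `"gpsm_experiment"`: per-model `"r20_result"`
#'   pairs with bootstrap CIs, the null curves, the split, and the
#'   training/reference MSAs.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  msa <- config$msa
  if (is.character(msa)) {
    fmt <- if (grepl("\\.(sto|stk|stockholm)$", msa)) "stockholm" else "fasta"
    msa <- read_msa(msa, format = fmt)
  }
  stopifnot(inherits(msa, "encoded_msa"))

  stage <- "split"
  res <- tryCatch({
    if (config$filter) {
      split <- phylo_split(msa, threshold = config$threshold,
                           train_size = config$train_size,
                           ref_size = config$ref_size,
                           seed = config$seeds$split)
      training <- `[.encoded_msa`(msa, split$train_survivors)
      reference <- `[.encoded_msa`(msa, split$ref_survivors)
    } else {
      N <- nrow(msa$codes)
      ref_size <- if (is.null(config$ref_size)) N %/% 2L else config$ref_size
      train_size <- if (is.null(config$train_size)) N - ref_size else
        config$train_size
      if (train_size + ref_size > N) stop("half sizes exceed MSA depth")
      perm <- .with_seed(config$seeds$split, sample.int(N))
      split <- list(train_survivors = sort(perm[seq_len(train_size)]),
                    ref_survivors = sort(perm[train_size +
                                                seq_len(ref_size)]))
      training <- `[.encoded_msa`(msa, split$train_survivors)
      reference <- `[.encoded_msa`(msa, split$ref_survivors)
    }
    if (nrow(training$codes) != nrow(reference$codes)) {
      warning("training and reference MSAs differ in depth")
    }
    eval_size <- if (is.null(config$eval_size)) nrow(reference$codes) else
      .check_count(config$eval_size, "eval_size")

    stage <- "fit"
    fits <- list()
    if ("potts" %in% config$models) {
      fits$potts <- do.call(fit_potts,
                            c(list(x = training,
                                   seed = config$seeds$fit),
                              config$potts_args))
    }
    if ("independent" %in% config$models) {
      fits$independent <- fit_independent(training)
    }

    stage <- "generate"
    evals <- list()
    for (m in names(fits)) {
      evals[[m]] <- simulate(fits[[m]], nsim = eval_size,
                             seed = config$seeds$generate)
    }

    stage <- "metric"
    psets <- position_sets(ncol(reference$codes), orders = config$orders,
                           n_sets = config$n_sets,
                           seed = config$seeds$metric)
    score <- function(ev, metric) {
      r20(reference, ev, orders = config$orders, top_k = config$top_k,
          position_sets = psets, metric = metric)
    }
    arms <- list()
    for (m in names(evals)) {
      arms[[m]] <- list(r20 = score(evals[[m]], "frequency"),
                        cc_r20 = score(evals[[m]], "connected"))
    }
    null <- list(r20 = score(training, "frequency"),
                 cc_r20 = score(training, "connected"))

    stage <- "bootstrap"
    cis <- lapply(arms, function(a) {
      list(r20 = r20_ci(a$r20, B = config$bootstrap,
                        seed = config$seeds$bootstrap),
           cc_r20 = r20_ci(a$cc_r20, B = config$bootstrap,
                           seed = config$seeds$bootstrap))
    })
    null_ci <- list(r20 = r20_ci(null$r20, B = config$bootstrap,
                                 seed = config$seeds$bootstrap),
                    cc_r20 = r20_ci(null$cc_r20, B = config$bootstrap,
                                    seed = config$seeds$bootstrap))

    structure(list(config = config, split = split, training = training,
                   reference = reference, fits = fits,
                   evaluations = evals, arms = arms, ci = cis,
                   null = null, null_ci = null_ci,
                   position_sets = psets),
              class = "gpsm_experiment")
  }, error = function(e) {
    stop(sprintf("experiment failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(config$out_dir)) .write_report(res, config$out_dir)
  res
}

.write_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_msa(x$training, file.path(dir, "training.fa"))
  write_msa(x$reference, file.path(dir, "reference.fa"))
  for (m in names(x$evaluations)) {
    write_msa(x$evaluations[[m]], file.path(dir, paste0("eval_", m, ".fa")))
  }
  rep <- list(
    null = list(r20 = x$null$r20$summary, cc_r20 = x$null$cc_r20$summary),
    arms = lapply(x$arms, function(a) {
      list(r20 = a$r20$summary, cc_r20 = a$cc_r20$summary)
    }),
    ci = x$ci, null_ci = x$null_ci,
    seeds = x$config$seeds
  )
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(NULL)
}

#' Score an external evaluation MSA against an experiment's reference
#'
#' Computes r20 and cc-r20 of any third-party MSA (e.g. sequences
#' generated by another model) against the experiment's reference, using
#' the experiment's stored position sets so numbers are directly
#' comparable to the internal arms.
#'
#' @param experiment A `"gpsm_experiment"`.
#' @param msa An [encoded_msa] or alignment file path with matching
#'   columns and alphabet.
#' @return List with `"r20_result"` entries `r20` and `cc_r20`.
#' @export
evaluate_external <- function(experiment, msa) {
  stopifnot(inherits(experiment, "gpsm_experiment"))
  if (is.character(msa)) msa <- read_msa(msa)
  stopifnot(inherits(msa, "encoded_msa"))
  if (!.same_frame(experiment$reference, msa)) {
    stop("external MSA does not match the experiment's columns/alphabet")
  }
  cfg <- experiment$config
  list(r20 = r20(experiment$reference, msa, orders = cfg$orders,
                 top_k = cfg$top_k,
                 position_sets = experiment$position_sets),
       cc_r20 = r20(experiment$reference, msa, orders = cfg$orders,
                    top_k = cfg$top_k,
                    position_sets = experiment$position_sets,
                    metric = "connected"))
}

#' @export
print.gpsm_experiment <- function(x, ...) {
  cat("GPSM evaluation experiment\n")
  cat(sprintf("  training %d x %d, reference %d x %d (filter: %s)\n",
              nrow(x$training$codes), ncol(x$training$codes),
              nrow(x$reference$codes), ncol(x$reference$codes),
              if (x$config$filter)
                sprintf("%.0f%%", 100 * x$config$threshold) else "off"))
  tab <- x$null$r20$summary[, c("order", "mean_r")]
  names(tab)[2L] <- "null"
  for (m in names(x$arms)) {
    tab[[m]] <- x$arms[[m]]$r20$summary$mean_r
  }
  cat("  r20 by order:\n")
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
#' @method plot gpsm_experiment
plot.gpsm_experiment <- function(x, metric = c("r20", "cc_r20"), ...) {
  metric <- match.arg(metric)
  null_res <- x$null[[metric]]
  plot(null_res, col = 1, lty = 2, main = metric, ...)
  cols <- seq_along(x$arms) + 1
  for (k in seq_along(x$arms)) {
    plot(x$arms[[k]][[metric]], add = TRUE, col = cols[k])
  }
  graphics::legend("bottomleft", bty = "n",
                   legend = c("null (training)", names(x$arms)),
                   col = c(1, cols), lty = c(2, rep(1, length(x$arms))))
  invisible(x)
}
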