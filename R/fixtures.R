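#' Default synthetic fixture configuration
#'
#' Three seeded scenarios sized like the mitochondrial COI study data this
#' package targets (hundreds of base pairs, tens of individuals), plus a
#' synthetic post-glacial temperature record:
#'
#' * `expansion_40x608`: 40 sequences x 608 sites under a strong logistic
#'   post-glacial expansion (theta_ancient 1e-4, theta_modern 2e-1,
#'   transition time 2.58e-4 subst/site), which yields star-like
#'   genealogies and segregating-site counts comparable to single-locus
#'   COI population samples.
#' * `constant_20x500`: constant-size control.
#' * `split_two_demes`: two demes of 15 and 25 samples separated at
#'   2.2e-3 subst/site (97 ky at 2.2e-8 subst/site/year).
#'
#' @param root_seed root seed; all fixture seeds derive from it via the
#'   package's seed splitter.
#' @return nested list describing the fixtures.
#' @export
default_fixture_config <- function(root_seed = 20191009) {
  list(
    root_seed = root_seed,
    subst = list(kappa = 10, base_frequencies = c(0.25, 0.15, 0.2, 0.4),
                 gamma_shape = 0.2),
    fixtures = list(
      expansion_40x608 = list(type = "expansion", n = 40, sites = 608,
                              theta_ancient = 1e-4, theta_modern = 2e-1,
                              transition_time = 2.58e-4, kind = "logistic"),
      constant_20x500 = list(type = "constant", n = 20, sites = 500,
                             theta = 2e-3),
      split_two_demes = list(type = "split", n1 = 15, n2 = 25, sites = 608,
                             split_time = 2.2e-3, deme_theta = 5e-4,
                             ancestral_theta = 1e-3)
    ),
    temperature = list(warming_onset = 12000, warming_width = 1000,
                       amplitude = 8, noise_sd = 0.3, span = 25000,
                       step = 100)
  )
}

#' Generate the synthetic fixture set on disk
#'
#' Writes, for every configured scenario, the FASTA alignment, the true
#' genealogy (Newick), and a row in the true-parameter table; plus the
#' synthetic temperature record (CSV) and a manifest enumerating every
#' fixture with its seed. Regeneration with the same config is
#' byte-identical.
#'
#' @param config a configuration list, see [default_fixture_config()].
#' @param outdir output directory (created if needed).
#' @return data.frame manifest, invisibly; also written as
#'   `manifest.tsv`.
#' @export
make_fixture_set <- function(config = default_fixture_config(), outdir) {
  if (!dir.exists(outdir))
    if (!dir.create(outdir, recursive = TRUE))
      stop_invalid("cannot create output directory %s", outdir)
  probe <- file.path(outdir, ".write_probe")
  ok <- tryCatch({ writeLines("x", probe); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_invalid("output directory %s is not writable", outdir)
  unlink(probe)
  sm <- substitution_model(config$subst$kappa, config$subst$base_frequencies,
                           config$subst$gamma_shape)
  manifest <- list()
  params <- list()
  idx <- 0L
  for (nm in names(config$fixtures)) {
    fx <- config$fixtures[[nm]]
    idx <- idx + 1L
    seed <- split_seed(config$root_seed, idx)
    fasta <- file.path(outdir, paste0(nm, ".fasta"))
    newick <- file.path(outdir, paste0(nm, ".nwk"))
    if (fx$type == "split") {
      hist <- split_history(fx$split_time,
                            list(fx$deme_theta, fx$deme_theta),
                            c(fx$n1, fx$n2), fx$ancestral_theta)
      sim <- simulate_split(hist, sm, fx$sites, seed = seed)
      aln <- sim$alignment
      gen <- sim$genealogy
      pops <- aln$populations
      utils::write.table(data.frame(label = aln$labels, population = pops),
                         file.path(outdir, paste0(nm, "_pops.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    } else {
      model <- if (fx$type == "expansion")
        two_epoch_model(fx$kind, theta_modern = fx$theta_modern,
                        theta_ancient = fx$theta_ancient,
                        transition_time = fx$transition_time)
      else
        two_epoch_model("exponential", fx$theta, fx$theta, 1e-3)
      gen <- simulate_coalescent(fx$n, model, seed = seed)
      aln <- simulate_sequences(gen, sm, fx$sites,
                                seed = split_seed(seed, 1))
    }
    write_fasta(aln, fasta)
    ape::write.tree(gen, file = newick)
    manifest[[nm]] <- data.frame(fixture = nm, type = fx$type, seed = seed,
                                 fasta = basename(fasta),
                                 newick = basename(newick),
                                 stringsAsFactors = FALSE)
    params[[nm]] <- data.frame(
      fixture = nm,
      parameter = names(unlist(fx[-1])),
      value = as.character(unlist(fx[-1])), stringsAsFactors = FALSE)
  }
  tseed <- split_seed(config$root_seed, 1000L)
  tc <- config$temperature
  rec <- synth_temperature(tc$warming_onset, tc$warming_width, tc$amplitude,
                           tc$noise_sd, tc$span, tc$step, seed = tseed)
  write_temperature_csv(rec, file.path(outdir, "temperature.csv"))
  manifest[["temperature"]] <- data.frame(fixture = "temperature",
                                          type = "temperature", seed = tseed,
                                          fasta = NA, newick = NA,
                                          stringsAsFactors = FALSE)
  man <- do.call(rbind, manifest)
  utils::write.table(man, file.path(outdir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(do.call(rbind, params),
                     file.path(outdir, "true_parameters.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(man)
}
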