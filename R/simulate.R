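#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so every generator is a pure function of its
#' arguments and seed.
#'
#' @param seed integer seed.
#' @param expr expression.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a baseline methylation cohort with planted response effects
#'
#' Draws a probes-by-subjects beta matrix at baseline. Each probe has a
#' latent mean; values are beta-distributed around it with concentration
#' `beta_precision` (mean m gives shapes `m*k, (1-m)*k`, so the expected
#' value is exactly m). For `n_informative` probes the responder-group mean
#' is shifted by `effect_delta`, with a random sign per probe so both
#' hyper- and hypo-methylated effects occur. Defaults mirror a 31-subject
#' cohort with 16 responders.
#'
#' @param n_subjects,n_responders cohort composition.
#' @param n_probes,n_informative probe counts.
#' @param effect_delta responder mean shift in beta units.
#' @param beta_precision beta-distribution concentration (larger = less
#'   sampling noise; 30 gives within-group SD of about 0.09 at mean 0.5).
#' @param seed integer seed.
#' @return list: `betas` (probes x samples), `sheet` (sample sheet, T1),
#'   `truth` (informative probe ids), `effect` (named signed shifts).
#' @export
sim_cohort <- function(n_subjects = 31, n_responders = 16,
                       n_probes = 2000, n_informative = 20,
                       effect_delta = 0.15, beta_precision = 30,
                       seed = 1) {
  stopifnot(n_responders <= n_subjects, n_informative <= n_probes,
            effect_delta >= 0, beta_precision > 0)
  with_seed(seed, {
    subjects <- sprintf("S%02d", seq_len(n_subjects))
    response <- rep(c("R", "NR"), c(n_responders, n_subjects - n_responders))
    probes <- sprintf("cg%08d", seq_len(n_probes))
    info <- if (n_informative > 0) sample(probes, n_informative) else character(0)
    base_mean <- stats::runif(n_probes, 0.10, 0.90)
    names(base_mean) <- probes
    shift <- stats::setNames(numeric(n_probes), probes)
    if (n_informative > 0) {
      sgn <- sample(c(-1, 1), n_informative, replace = TRUE)
      prop <- base_mean[info] + sgn * effect_delta
      flip <- prop < 0.02 | prop > 0.98
      sgn[flip] <- -sgn[flip]
      prop <- base_mean[info] + sgn * effect_delta
      if (any(prop < 0.02 | prop > 0.98))
        stop("effect_delta infeasible for drawn probe means")
      shift[info] <- sgn * effect_delta
    }
    mu <- matrix(base_mean, n_probes, n_subjects,
                 dimnames = list(probes, subjects))
    mu[, response == "R"] <- mu[, response == "R"] + shift
    k <- beta_precision
    betas <- matrix(stats::rbeta(length(mu), mu * k, (1 - mu) * k),
                    n_probes, n_subjects, dimnames = dimnames(mu))
    sheet <- data.frame(sample_id = paste0(subjects, "_T1"),
                        subject_id = subjects, timepoint = "T1",
                        response = response, stringsAsFactors = FALSE)
    colnames(betas) <- sheet$sample_id
    list(betas = betas, sheet = sheet, truth = sort(info), effect = shift)
  })
}

#' Simulate longitudinal replicates with a target intraclass correlation
#'
#' Expands a baseline beta matrix to `n_timepoints` occasions per subject.
#' On the logit scale each probe's observed between-subject spread is
#' decomposed into a persistent subject effect (variance fraction
#' `icc_target`) and an occasion effect (fraction `1 - icc_target`), then
#' squashed back to (0,1). `icc_target = 1` reproduces the baseline values
#' at every timepoint.
#'
#' @param base probes x subjects beta matrix (e.g. `sim_cohort()$betas`).
#' @param icc_target target intraclass correlation in \[0, 1\].
#' @param n_timepoints occasions per subject (named T1, T2, ...).
#' @param seed integer seed.
#' @return probes x (subjects * timepoints) beta matrix; columns named
#'   `<subject>_T<t>` (any `_T1` suffix of the input columns is stripped).
#' @export
sim_longitudinal <- function(base, icc_target = 0.9, n_timepoints = 3,
                             seed = 1) {
  stopifnot(icc_target >= 0, icc_target <= 1, n_timepoints >= 2)
  with_seed(seed, {
    subjects <- sub("_T1$", "", colnames(base))
    eps <- 1e-4
    l <- stats::qlogis(pmin(pmax(base, eps), 1 - eps))
    mu <- rowMeans(l)
    d <- l - mu
    s <- apply(d, 1, stats::sd)
    z <- d / ifelse(s > 0, s, 1)
    tp <- paste0("T", seq_len(n_timepoints))
    out <- matrix(NA_real_, nrow(base), ncol(base) * n_timepoints,
                  dimnames = list(rownames(base),
                                  paste(rep(subjects, each = n_timepoints),
                                        rep(tp, length(subjects)), sep = "_")))
    for (i in seq_along(subjects)) {
      e <- matrix(stats::rnorm(nrow(base) * n_timepoints),
                  nrow(base), n_timepoints)
      lat <- mu + s * (sqrt(icc_target) * z[, i] +
                         sqrt(1 - icc_target) * e)
      out[, (i - 1) * n_timepoints + seq_len(n_timepoints)] <- stats::plogis(lat)
    }
    out
  })
}

#' Simulate a cell-type reference signature
#'
#' Six blood cell types by default (CD8T, CD4T, NK, B, Mono, Neu), each
#' with `markers_per_type` probes methylated high in that type (0.85) and
#' low elsewhere (0.15), plus shared non-discriminating filler probes.
#'
#' @param cell_types character vector of cell-type labels.
#' @param markers_per_type discriminating probes per type.
#' @param n_filler non-discriminating probes shared across types.
#' @param seed integer seed.
#' @return cell-type x probe matrix of reference beta means.
#' @export
sim_cell_reference <- function(cell_types = c("CD8T", "CD4T", "NK", "B",
                                              "Mono", "Neu"),
                               markers_per_type = 50, n_filler = 60,
                               seed = 1) {
  with_seed(seed, {
    t <- length(cell_types)
    n_probes <- t * markers_per_type + n_filler
    probes <- sprintf("cg%08d", 1e6 + seq_len(n_probes))
    ref <- matrix(0.15, t, n_probes, dimnames = list(cell_types, probes))
    for (i in seq_len(t)) {
      idx <- (i - 1) * markers_per_type + seq_len(markers_per_type)
      ref[i, idx] <- 0.85
    }
    if (n_filler > 0) {
      fill <- t * markers_per_type + seq_len(n_filler)
      ref[, fill] <- matrix(rep(stats::runif(n_filler, 0.2, 0.8), each = t),
                            t, n_filler)
    }
    ref
  })
}

#' Simulate whole-blood samples as convex cell-type mixtures
#'
#' Sample proportions are Dirichlet-distributed; the observed beta value is
#' the proportion-weighted mix of the reference signatures plus Gaussian
#' noise, clipped to \[0, 1\].
#'
#' @param reference cell-type x probe signature matrix.
#' @param n_samples number of mixture samples.
#' @param dirichlet_alpha scalar or per-type concentration.
#' @param noise_sd measurement noise SD in beta units.
#' @param seed integer seed.
#' @return list: `betas` (probes x samples), `proportions`
#'   (samples x cell types, the ground truth).
#' @export
sim_cell_mixture <- function(reference, n_samples = 100,
                             dirichlet_alpha = 2, noise_sd = 0.02,
                             seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  with_seed(seed, {
    t <- nrow(reference)
    alpha <- if (length(dirichlet_alpha) == 1)
      rep(dirichlet_alpha, t) else dirichlet_alpha
    w <- .rdirichlet(n_samples, alpha)
    colnames(w) <- rownames(reference)
    rownames(w) <- sprintf("mix%03d", seq_len(n_samples))
    betas <- t(w %*% reference)
    if (noise_sd > 0)
      betas <- betas + stats::rnorm(length(betas), 0, noise_sd)
    betas <- pmin(pmax(betas, 0), 1)
    colnames(betas) <- rownames(w)
    list(betas = betas, proportions = w)
  })
}

# Draw one clinical record whose three response criteria equal the target
# logical flags. Scores stay inside their index ranges.
.sim_record <- function(endo, bio, clin) {
  ems_t1 <- sample(2:3, 1)
  uceis_t1 <- sample(4:8, 1)
  if (endo) {
    ems_t2 <- max(0L, ems_t1 - sample(1:2, 1))
    uceis_t2 <- max(0L, uceis_t1 - sample(2:4, 1))
  } else {
    ems_t2 <- ems_t1
    uceis_t2 <- uceis_t1 - sample(0:1, 1)
  }
  if (bio) {
    crp_t1 <- stats::runif(1, 6, 30)
    crp_t2 <- crp_t1 * stats::runif(1, 0.1, 0.5)
    fcal_t1 <- stats::runif(1, 500, 5000)
    fcal_t2 <- fcal_t1 * stats::runif(1, 0.1, 0.5)
  } else {
    crp_t1 <- stats::runif(1, 12, 30)
    crp_t2 <- crp_t1 * stats::runif(1, 0.6, 0.9)   # > 5 mg/L, < 50% drop
    fcal_t1 <- stats::runif(1, 600, 4000)
    fcal_t2 <- fcal_t1 * stats::runif(1, 0.6, 0.9) # > 250 ug/g
  }
  mayo_t1 <- sample(7:12, 1)
  sccai_t1 <- sample(8:13, 1)
  if (clin) {
    if (stats::runif(1) < 0.5) {  # total-Mayo route
      drop <- max(3, ceiling(0.30 * mayo_t1)) + sample(0:2, 1)
      mayo_t2 <- max(0L, mayo_t1 - as.integer(drop))
      rbs_t1 <- sample(1:3, 1)
      rbs_t2 <- sample(0:1, 1)
      sccai_t2 <- ceiling(sccai_t1 * stats::runif(1, 0.6, 0.9))
    } else {                      # SCCAI route
      mayo_t2 <- mayo_t1 - sample(0:2, 1)
      rbs_t1 <- sample(2:3, 1)
      rbs_t2 <- rbs_t1
      sccai_t2 <- floor(sccai_t1 * stats::runif(1, 0.2, 0.5))
    }
  } else {
    mayo_t2 <- mayo_t1 - sample(0:2, 1)
    rbs_t1 <- sample(2:3, 1)
    rbs_t2 <- rbs_t1
    sccai_t2 <- ceiling(sccai_t1 * stats::runif(1, 0.6, 0.9))
  }
  data.frame(ems_t1 = ems_t1, ems_t2 = ems_t2,
             uceis_t1 = uceis_t1, uceis_t2 = uceis_t2,
             mayo_t1 = mayo_t1, mayo_t2 = mayo_t2,
             rbs_t1 = rbs_t1, rbs_t2 = rbs_t2,
             sccai_t1 = sccai_t1, sccai_t2 = sccai_t2,
             crp_t1 = crp_t1, crp_t2 = crp_t2,
             fcal_t1 = fcal_t1, fcal_t2 = fcal_t2)
}

#' Simulate clinical records consistent with assigned response labels
#'
#' Responders satisfy the endoscopic criterion plus at least one of the
#' clinical/biochemical criteria; non-responders either fail the
#' endoscopic criterion or fail both the clinical and biochemical
#' criteria (the two ways the composite endpoint can be missed).
#'
#' @param labels character vector of "R"/"NR" per subject.
#' @param subject_ids subject identifiers (default `S01...`).
#' @param seed integer seed.
#' @return data.frame of clinical records, one row per subject, including
#'   `subject_id`, `response` (the assigned label), `steroid` and `sccai`
#'   (baseline SCCAI).
#' @export
sim_clinical <- function(labels,
                         subject_ids = sprintf("S%02d", seq_along(labels)),
                         seed = 1) {
  stopifnot(all(labels %in% c("R", "NR")),
            length(labels) == length(subject_ids))
  with_seed(seed, {
    rows <- lapply(labels, function(lab) {
      if (lab == "R") {
        pick <- sample(1:3, 1)  # which of clinical/biochemical holds
        .sim_record(endo = TRUE, bio = pick %in% c(1, 3),
                    clin = pick %in% c(2, 3))
      } else if (stats::runif(1) < 0.5) {
        .sim_record(endo = FALSE,
                    bio = stats::runif(1) < 0.5,
                    clin = stats::runif(1) < 0.5)
      } else {
        .sim_record(endo = TRUE, bio = FALSE, clin = FALSE)
      }
    })
    rec <- do.call(rbind, rows)
    cbind(data.frame(subject_id = subject_ids, response = labels,
                     steroid = stats::rbinom(length(labels), 1, 0.5),
                     stringsAsFactors = FALSE),
          rec, data.frame(sccai = rec$sccai_t1))
  })
}

#' Simulate probes with gap (multi-modal) beta signals
#'
#' A designated fraction of probes show two beta clusters separated by
#' `gap_size` (emulating probes tracking an underlying genetic variant);
#' the rest are unimodal with tight jitter.
#'
#' @param n_probes total probe count.
#' @param gap_fraction fraction of probes given a gap signal.
#' @param gap_size separation between the cluster centres (beta units).
#' @param n_samples samples per probe.
#' @param seed integer seed.
#' @return list: `betas` (probes x samples), `truth` (gap probe ids).
#' @export
sim_gap_probes <- function(n_probes = 200, gap_fraction = 0.1,
                           gap_size = 0.5, n_samples = 31, seed = 1) {
  stopifnot(gap_fraction >= 0, gap_fraction <= 1, gap_size >= 0)
  with_seed(seed, {
    probes <- sprintf("gap%05d", seq_len(n_probes))
    samples <- sprintf("S%02d", seq_len(n_samples))
    n_gap <- round(gap_fraction * n_probes)
    gap_ids <- if (n_gap > 0) sample(probes, n_gap) else character(0)
    betas <- matrix(NA_real_, n_probes, n_samples,
                    dimnames = list(probes, samples))
    for (p in probes) {
      jitter <- stats::runif(n_samples, -0.02, 0.02)
      if (p %in% gap_ids) {
        c1 <- stats::runif(1, 0.05, 0.95 - gap_size)
        grp <- stats::rbinom(n_samples, 1, 0.5)
        if (length(unique(grp)) == 1) grp[1] <- 1 - grp[1]
        betas[p, ] <- c1 + grp * gap_size + jitter
      } else {
        betas[p, ] <- stats::runif(1, 0.2, 0.8) + jitter
      }
      betas[p, ] <- pmin(pmax(betas[p, ], 0), 1)
    }
    list(betas = betas, truth = sort(gap_ids))
  })
}
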