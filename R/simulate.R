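#' Simulation design for synthetic microbiome count data
#'
#' Specifies a logistic-normal-multinomial generator with block-structured
#' basis correlation that differs between two groups: log-normal basis
#' abundances (the model SparCC itself assumes, which keeps
#' parameter-recovery checks interpretable) are converted to compositional
#' fractions and sampled multinomially at log-normally drawn sequencing
#' depths, with optional structural zeros. A block of planted taxa is
#' correlated within one group but not the other — the differential
#' connectivity signal — and covariates may be associated with group
#' membership.
#'
#' @param n_per_group samples per group (default 40).
#' @param p number of taxa (default 30).
#' @param dc_taxa indices of the planted differentially connected block
#'   (default `1:5`; use `integer(0)` for a null design).
#' @param dc_cor within-block basis correlation per group, named vector
#'   `c(A = , B = )` (default 0.7 in A, 0 in B).
#' @param base_cor background basis correlation between all other pairs
#'   (default 0).
#' @param sigma2 basis log-abundance variance (default 1).
#' @param mu_sd spread (sd) of per-taxon log-abundance means, drawn once from
#'   the design seed; heterogeneous means give the uneven taxon fractions
#'   typical of 16S data (default 1).
#' @param depth_meanlog,depth_sdlog log-normal law of sequencing depth
#'   (defaults `log(1e4)` and 0.5, i.e. median depth 10,000 reads).
#' @param zero_inflation baseline probability that a sampled count is
#'   replaced by a structural zero; the effective dropout probability decays
#'   with the sampled count (`zero_inflation * exp(-count / 10)`), so
#'   dropout affects rare cells, never dominant taxa (default 0.05).
#' @param covariate_effect difference in the numeric covariate's mean between
#'   groups, in units of its sd (default 0.5: a mildly confounded covariate).
#' @param subject_sd sd of the per-subject log-abundance random intercept
#'   shared across timepoints in the paired generator (default 0.5).
#' @param seed integer seed.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(n_per_group = 40L, p = 30L, dc_taxa = 1:5,
                              dc_cor = c(A = 0.7, B = 0), base_cor = 0,
                              sigma2 = 1, mu_sd = 1,
                              depth_meanlog = log(1e4), depth_sdlog = 0.5,
                              zero_inflation = 0.05, covariate_effect = 0.5,
                              subject_sd = 0.5, seed = 1L) {
  stopifnot(n_per_group >= 4, p >= 4, all(dc_taxa %in% seq_len(p)),
            all(abs(dc_cor) < 1), abs(base_cor) < 1, sigma2 > 0,
            zero_inflation >= 0, zero_inflation < 1)
  structure(list(n_per_group = as.integer(n_per_group), p = as.integer(p),
                 dc_taxa = as.integer(dc_taxa), dc_cor = dc_cor,
                 base_cor = base_cor, sigma2 = sigma2, mu_sd = mu_sd,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 zero_inflation = zero_inflation,
                 covariate_effect = covariate_effect,
                 subject_sd = subject_sd, seed = as.integer(seed)),
            class = "simulation_design")
}

# Basis correlation matrix for one group; errors before sampling if the
# implied covariance is not positive definite.
basis_correlation <- function(design, group = c("A", "B"), extra_shift = 0) {
  group <- match.arg(group)
  p <- design$p
  R <- matrix(design$base_cor, p, p)
  blk <- design$dc_taxa
  if (length(blk) > 1) {
    r <- unname(design$dc_cor[group]) + extra_shift
    R[blk, blk] <- r
  }
  diag(R) <- 1
  ok <- tryCatch({ chol(R); TRUE }, error = function(e) FALSE)
  if (!ok) stop("design correlation matrix is not positive definite")
  R
}

# Draw one group's count block. Returns counts plus the latent fractions.
draw_group_counts <- function(n, mu, Sigma_chol, design, subject_effect = NULL) {
  p <- design$p
  counts <- matrix(0, n, p)
  fracs <- matrix(0, n, p)
  for (i in seq_len(n)) {
    repeat {
      w <- mu + drop(stats::rnorm(p) %*% Sigma_chol)
      if (!is.null(subject_effect)) w <- w + subject_effect[i, ]
      f <- exp(w - max(w)); f <- f / sum(f)
      depth <- max(50, round(stats::rlnorm(1, design$depth_meanlog,
                                           design$depth_sdlog)))
      x <- drop(stats::rmultinom(1, depth, f))
      if (design$zero_inflation > 0) {
        # abundance-dependent dropout: structural zeros hit rare cells
        # (a taxon at high relative abundance is never zeroed by dropout)
        p_drop <- design$zero_inflation * exp(-x / 10)
        x[stats::runif(p) < p_drop] <- 0
      }
      if (sum(x) > 0) { counts[i, ] <- x; fracs[i, ] <- f; break }
    }
  }
  list(counts = counts, fractions = fracs)
}

sim_metadata <- function(design, groups) {
  n <- length(groups)
  z <- as.integer(groups == "A")
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             group = ifelse(z == 1, "grpA", "grpB"),
             x_num = stats::rnorm(n, mean = design$covariate_effect * z),
             x_cat = sample(c("u", "v"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate a two-group microbiome count dataset
#'
#' @param design a [simulation_design()].
#' @return list with `counts` (a [count_table]), `meta` (data.frame with
#'   `sample_id`, `group`, a numeric covariate `x_num` shifted between
#'   groups, and a categorical covariate `x_cat`), and `truth` (planted DC
#'   taxa, generating correlation matrices, latent per-sample fractions, and
#'   the design).
#' @export
simulate_dcnet <- function(design = simulation_design()) {
  R_A <- basis_correlation(design, "A")
  R_B <- basis_correlation(design, "B")
  with_seed(design$seed, {
    mu <- stats::rnorm(design$p, 0, design$mu_sd)
    ch_A <- chol(design$sigma2 * R_A)
    ch_B <- chol(design$sigma2 * R_B)
    n_g <- design$n_per_group
    ga <- draw_group_counts(n_g, mu, ch_A, design)
    gb <- draw_group_counts(n_g, mu, ch_B, design)
    groups <- rep(c("A", "B"), each = n_g)
    meta <- sim_metadata(design, groups)
    counts <- rbind(ga$counts, gb$counts)
    rownames(counts) <- meta$sample_id
    colnames(counts) <- sprintf("taxon%02d", seq_len(design$p))
    list(counts = count_table(counts),
         meta = meta,
         truth = list(dc_taxa = colnames(counts)[design$dc_taxa],
                      cor_A = R_A, cor_B = R_B,
                      fractions = rbind(ga$fractions, gb$fractions),
                      mu = mu, design = design))
  })
}

#' Simulate a paired two-timepoint microbiome dataset
#'
#' Subject-level random intercepts are shared across timepoints; at
#' timepoint 2 the planted block's basis correlation is altered by
#' `t2_shift` in one group only, so connectivity *changes* differentially —
#' the signal the difference-of-association-matrices mode targets.
#'
#' @param design a [simulation_design()].
#' @param t2_shift additive change of the block correlation at timepoint 2
#'   (default 0: a null paired design).
#' @param shift_group which group receives the shift (default `"A"`).
#' @return list with `counts_t1`, `counts_t2` (row-aligned [count_table]s,
#'   one row per subject), `counts_long` (both stacked, record-level sample
#'   ids), `meta_long` (one row per record: `sample_id`, `subject_id`,
#'   `time`, `group`, covariates), and `truth`.
#' @export
simulate_dcnet_paired <- function(design = simulation_design(),
                                  t2_shift = 0, shift_group = c("A", "B")) {
  shift_group <- match.arg(shift_group)
  R1 <- list(A = basis_correlation(design, "A"),
             B = basis_correlation(design, "B"))
  R2 <- list(A = basis_correlation(design, "A",
                                   if (shift_group == "A") t2_shift else 0),
             B = basis_correlation(design, "B",
                                   if (shift_group == "B") t2_shift else 0))
  with_seed(design$seed, {
    mu <- stats::rnorm(design$p, 0, design$mu_sd)
    n_g <- design$n_per_group
    blocks <- list()
    for (g in c("A", "B")) {
      bsub <- matrix(stats::rnorm(n_g * design$p, 0, design$subject_sd),
                     n_g, design$p)
      blocks[[g]] <- list(
        t1 = draw_group_counts(n_g, mu, chol(design$sigma2 * R1[[g]]),
                               design, subject_effect = bsub),
        t2 = draw_group_counts(n_g, mu, chol(design$sigma2 * R2[[g]]),
                               design, subject_effect = bsub))
    }
    subj <- sprintf("subj%03d", seq_len(2 * n_g))
    groups <- rep(c("A", "B"), each = n_g)
    meta_subj <- sim_metadata(design, groups)
    taxa <- sprintf("taxon%02d", seq_len(design$p))
    c1 <- rbind(blocks$A$t1$counts, blocks$B$t1$counts)
    c2 <- rbind(blocks$A$t2$counts, blocks$B$t2$counts)
    rownames(c1) <- rownames(c2) <- subj
    colnames(c1) <- colnames(c2) <- taxa
    long <- rbind(c1, c2)
    rownames(long) <- c(paste0(subj, "_t1"), paste0(subj, "_t2"))
    meta_long <- data.frame(
      sample_id = rownames(long),
      subject_id = rep(subj, 2),
      time = rep(c("t1", "t2"), each = 2 * n_g),
      group = rep(meta_subj$group, 2),
      x_num = rep(meta_subj$x_num, 2),
      x_cat = rep(meta_subj$x_cat, 2),
      stringsAsFactors = FALSE)
    list(counts_t1 = count_table(c1), counts_t2 = count_table(c2),
         counts_long = count_table(long), meta_long = meta_long,
         truth = list(dc_taxa = taxa[design$dc_taxa],
                      cor_t1 = R1, cor_t2 = R2, mu = mu, design = design))
  })
}
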