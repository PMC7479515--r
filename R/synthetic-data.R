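#' Build a synthetic genome specification
#'
#' Lays out a gene universe over chromosomes with p/q arms and plants named
#' gene modules in it: marker sets for common non-malignant brain cell types
#' (microglia, T cells, OPCs, oligodendrocytes, endothelial cells — synthetic
#' analogues of the canonical marker genes), tumor expression-program modules
#' including S-phase and G2M cell-cycle modules, and a housekeeping set. All
#' modules are disjoint. Gene positions strictly increase within each
#' chromosome and the gene-to-chromosome assignment is a partition.
#'
#' @param n_genes total number of genes (default 6000).
#' @param n_chromosomes number of chromosomes (default 10); genes are split
#'   as evenly as possible, each chromosome split into a p and a q arm.
#' @param module_sizes named integer vector of module sizes. The defaults
#'   plant five 10-gene normal-type marker sets, five 30-gene tumor program
#'   modules, 30-gene S and G2M modules, and 50 housekeeping genes.
#' @param seed integer seed; the layout is deterministic given the seed.
#' @return object of class `genome_spec`: list with `genes` (tibble:
#'   `gene_id`, `chrom`, `arm`, `start`, `end`), `modules` (named list of
#'   gene-id vectors), `chromosomes` (tibble), `n_genes`, `seed`.
#' @export
make_genome <- function(n_genes = 6000, n_chromosomes = 10,
                        module_sizes = NULL, seed = 1) {
  if (is.null(module_sizes)) {
    module_sizes <- c(
      microglia = 10, tcell = 10, opc = 10, oligodendrocyte = 10,
      endothelial = 10,
      NSC = 30, glial = 30, ependymal = 30, neuronal = 30, metabolic = 30,
      S = 30, G2M = 30,
      housekeeping = 50
    )
  }
  if (is.null(names(module_sizes)) || any(names(module_sizes) == "")) {
    stop("`module_sizes` must be a named vector", call. = FALSE)
  }
  if (sum(module_sizes) > n_genes) {
    stop("module sizes (", sum(module_sizes), ") exceed n_genes (", n_genes, ")",
         call. = FALSE)
  }
  if (n_chromosomes < 1) stop("need at least one chromosome", call. = FALSE)

  with_seed(seed, {
    gene_id <- sprintf("g%05d", seq_len(n_genes))
    chrom_sizes <- diff(round(seq(0, n_genes, length.out = n_chromosomes + 1)))
    chrom <- rep(paste0("chr", seq_len(n_chromosomes)), chrom_sizes)
    # positions strictly increasing within a chromosome
    start <- unlist(lapply(chrom_sizes, function(k) {
      cumsum(sample(1000:10000, k, replace = TRUE))
    }), use.names = FALSE)
    genes <- tibble::tibble(
      gene_id = gene_id, chrom = chrom,
      start = start, end = start + 999L
    )
    genes <- genes |>
      dplyr::group_by(.data$chrom) |>
      dplyr::mutate(arm = ifelse(dplyr::row_number() <=
                                   ceiling(dplyr::n() * 0.4), "p", "q")) |>
      dplyr::ungroup() |>
      dplyr::select("gene_id", "chrom", "arm", "start", "end")

    # modules spread across the genome so no single arm owns a module
    pool <- sample(gene_id)
    modules <- list()
    offset <- 0L
    for (nm in names(module_sizes)) {
      k <- module_sizes[[nm]]
      modules[[nm]] <- sort(pool[offset + seq_len(k)])
      offset <- offset + k
    }
    chromosomes <- genes |>
      dplyr::count(.data$chrom, .data$arm, name = "n_genes") |>
      tidyr::pivot_wider(names_from = "arm", values_from = "n_genes",
                         names_prefix = "n_")
    structure(
      list(genes = genes, modules = modules, chromosomes = chromosomes,
           n_genes = n_genes, seed = seed),
      class = "genome_spec"
    )
  })
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d genes on %d chromosomes; modules: %s\n",
              x$n_genes, dplyr::n_distinct(x$genes$chrom),
              paste(names(x$modules), collapse = ", ")))
  invisible(x)
}

#' Describe one sample for the cell simulator
#'
#' @param sample_id sample name.
#' @param compartment anatomical compartment label (PF, ST or SP).
#' @param malignant named integer vector: cells per tumor program module.
#' @param normal named integer vector: cells per normal cell type.
#' @param cna data frame with columns `arm` (e.g. `"chr1q"`) and
#'   `multiplier` (> 0; 1.5 for a gain, 0.5 for a loss); applied to all
#'   malignant cells of the sample.
#' @param cycling_frac fraction of malignant cells that additionally
#'   up-regulate a randomly chosen cell-cycle module (S or G2M).
#' @return a one-sample design (list), to be combined with [list()].
#' @export
sample_design <- function(sample_id, compartment = "PF",
                          malignant = c(NSC = 50, ependymal = 50),
                          normal = c(microglia = 10, oligodendrocyte = 10),
                          cna = data.frame(arm = "chr1q", multiplier = 1.5),
                          cycling_frac = 0.1) {
  if (!is.null(cna) && nrow(cna) > 0 && any(cna$multiplier <= 0)) {
    stop("CNA multipliers must be positive", call. = FALSE)
  }
  list(sample_id = sample_id, compartment = compartment,
       malignant = malignant, normal = normal,
       cna = cna, cycling_frac = cycling_frac)
}

#' Simulate a single-cell TPM cohort with planted ground truth
#'
#' Baseline per-gene means are log-normal; malignant cells fold up the genes
#' of their planted program module (and, for cycling cells, an S or G2M
#' module); chromosome-arm copy-number events multiply the expected
#' expression of every gene on the arm before counts are drawn; counts are
#' negative-binomial and renormalized so each cell's TPM sums to 1e6.
#' Normal cells fold up their cell-type marker module and carry no CNA.
#'
#' @param genome a [make_genome()] result.
#' @param design list of [sample_design()] entries.
#' @param fold_up expression fold-change applied to a cell's module genes
#'   (>= 1; 1 plants no module signal; default 4).
#' @param noise list: `meanlog`/`sdlog` of the baseline log-normal gene
#'   means, `dispersion` (negative-binomial; 0 gives Poisson counts),
#'   `lib_size` (expected counts per cell), `sample_sdlog` (per-sample
#'   log-normal mean shift).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list: `expr` (`expr_mat`, TPM, with compartment labels), `cells`
#'   (tibble of per-cell truth: `cell_id`, `sample_id`, `compartment`,
#'   `class`, `normal_type`, `program`, `cycling`, `cna` list-column),
#'   `genes` (annotation tibble `gene_id`, `chrom`, `arm`, `start`, `end`).
#' @export
simulate_cells <- function(genome, design, fold_up = 4,
                           noise = list(), seed = 1) {
  stopifnot(inherits(genome, "genome_spec"))
  if (length(design) == 0) stop("empty design", call. = FALSE)
  if (fold_up < 1) stop("fold_up must be at least 1", call. = FALSE)
  noise <- utils::modifyList(
    list(meanlog = 1, sdlog = 1.2, dispersion = 0.3,
         lib_size = 2e5, sample_sdlog = 0.1),
    noise
  )
  genes <- genome$genes
  n_genes <- nrow(genes)
  with_seed(seed, {
    baseline <- stats::rlnorm(n_genes, noise$meanlog, noise$sdlog)
    names(baseline) <- genes$gene_id
    # housekeeping genes are constitutively high so QC has signal
    hk <- genome$modules$housekeeping
    if (!is.null(hk)) baseline[hk] <- baseline[hk] * 8

    arm_key <- paste0(genes$chrom, genes$arm)
    cells_list <- list()
    cols <- list()
    for (d in design) {
      shift <- stats::rlnorm(n_genes, 0, noise$sample_sdlog)
      cna <- d$cna
      cna_mult <- rep(1, n_genes)
      if (!is.null(cna) && nrow(cna) > 0) {
        for (i in seq_len(nrow(cna))) {
          cna_mult[arm_key == cna$arm[i]] <- cna$multiplier[i]
        }
      }
      roster <- rbind(
        if (length(d$malignant))
          data.frame(class = "malignant",
                     label = rep(names(d$malignant), d$malignant)),
        if (length(d$normal))
          data.frame(class = "normal", label = rep(names(d$normal), d$normal))
      )
      if (is.null(roster) || nrow(roster) == 0) {
        stop("sample ", d$sample_id, " has no cells", call. = FALSE)
      }
      for (j in seq_len(nrow(roster))) {
        cls <- roster$class[j]
        lab <- roster$label[j]
        mod <- genome$modules[[lab]]
        if (is.null(mod)) stop("unknown module: ", lab, call. = FALSE)
        mu <- baseline * shift
        mu[mod] <- mu[mod] * fold_up
        cycling <- FALSE
        if (cls == "malignant") {
          mu <- mu * cna_mult
          if (stats::runif(1) < d$cycling_frac) {
            cycling <- TRUE
            cc <- genome$modules[[sample(c("S", "G2M"), 1)]]
            mu[cc] <- mu[cc] * fold_up
          }
        }
        p <- mu / sum(mu)
        counts <- if (noise$dispersion <= 0) {
          stats::rpois(n_genes, p * noise$lib_size)
        } else {
          stats::rnbinom(n_genes, mu = p * noise$lib_size,
                         size = 1 / noise$dispersion)
        }
        tpm <- counts / max(sum(counts), 1) * 1e6
        cid <- sprintf("%s_c%04d", d$sample_id, j)
        cols[[cid]] <- tpm
        cells_list[[cid]] <- tibble::tibble(
          cell_id = cid, sample_id = d$sample_id,
          compartment = d$compartment, class = cls,
          normal_type = if (cls == "normal") lab else NA_character_,
          program = if (cls == "malignant") lab else NA_character_,
          cycling = cycling,
          cna = list(if (cls == "malignant" && !is.null(cna)) cna
                     else data.frame(arm = character(), multiplier = numeric()))
        )
      }
    }
    expr <- do.call(cbind, cols)
    rownames(expr) <- genes$gene_id
    cells <- dplyr::bind_rows(cells_list)
    list(
      expr = expression_matrix(expr, "tpm",
                               compartment = cells$compartment),
      cells = cells,
      genes = genes
    )
  })
}

#' Simulate a binarized regulon-activity matrix
#'
#' A stand-in for binarized per-cell regulon activity (as produced by
#' AUCell-style thresholding): each regulon is active with probability
#' `p_on` in cells of its target program and inactive elsewhere, then every
#' entry is flipped independently with probability `flip_noise`.
#'
#' @param cells per-cell truth tibble from [simulate_cells()] (needs
#'   `cell_id` and `program`).
#' @param regulon_design tibble/data.frame with columns `regulon`,
#'   `program`, `p_on`.
#' @param flip_noise probability of flipping an entry (default 0).
#' @param seed integer seed.
#' @return binary integer matrix, cells in rows, regulons in columns.
#' @export
simulate_regulons <- function(cells, regulon_design, flip_noise = 0, seed = 1) {
  if (any(regulon_design$p_on < 0 | regulon_design$p_on > 1)) {
    stop("p_on must lie in [0, 1]", call. = FALSE)
  }
  if (flip_noise < 0 || flip_noise > 1) {
    stop("flip_noise must lie in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    n <- nrow(cells)
    out <- matrix(0L, n, nrow(regulon_design),
                  dimnames = list(cells$cell_id, regulon_design$regulon))
    for (j in seq_len(nrow(regulon_design))) {
      on <- !is.na(cells$program) &
        cells$program == regulon_design$program[j]
      out[on, j] <- stats::rbinom(sum(on), 1, regulon_design$p_on[j])
    }
    if (flip_noise > 0) {
      flips <- matrix(stats::rbinom(length(out), 1, flip_noise),
                      nrow = n)
      out <- abs(out - flips)
      storage.mode(out) <- "integer"
    }
    out
  })
}

#' Simulate a bulk expression cohort with survival outcomes
#'
#' Each bulk sample is a composition-weighted mixture of program mean
#' profiles (baseline log-normal gene means with the program module folded
#' up) with multiplicative log-normal noise, renormalized to TPM. Survival
#' times are exponential with hazard
#' `baseline_hazard * exp(beta * fraction_of_target_program)`; censoring is
#' an independent exponential whose rate is chosen so that, at `beta = 0`,
#' the expected censored fraction equals `censor_rate`.
#'
#' By default compositions come from a two-component Dirichlet mixture:
#' half the cohort is target-program-high (mean fraction
#' `target_frac_high`), half target-program-low (`target_frac_low`),
#' emulating the distinct high- and low-expressing patient groups that
#' signature stratification of bulk cohorts is built to separate. Passing
#' an explicit `composition_prior` replaces the mixture with a single
#' Dirichlet draw.
#'
#' @param genome a [make_genome()] result.
#' @param n_samples number of bulk samples (>= 2).
#' @param programs program module names mixed in each sample.
#' @param target_program the program whose fraction drives the hazard.
#' @param composition_prior optional Dirichlet concentration (named, over
#'   `programs`); a single-program prior degenerates with a warning.
#' @param target_frac_high,target_frac_low mean target fraction of the two
#'   mixture components (defaults 0.8 and 0.05).
#' @param concentration Dirichlet concentration of each mixture component
#'   (default 25; larger = tighter compositions).
#' @param beta log-hazard coefficient on the target-program fraction.
#' @param baseline_hazard baseline exponential hazard (> 0, per month).
#' @param censor_rate expected censored fraction at `beta = 0`.
#' @param fold_up module fold-up in program profiles (default 4).
#' @param noise_sdlog per-gene log-normal measurement noise (default 0.2).
#' @param seed integer seed.
#' @return list: `expr` (`expr_mat` TPM, genes x samples), `samples`
#'   (tibble: `sample_id`, fractions per program, `frac_target`, `time`
#'   in months, `event`).
#' @export
simulate_bulk_cohort <- function(genome, n_samples = 200,
                                 programs = c("NSC", "ependymal", "neuronal"),
                                 target_program = "ependymal",
                                 composition_prior = NULL,
                                 target_frac_high = 0.8,
                                 target_frac_low = 0.05,
                                 concentration = 25,
                                 beta = log(3), baseline_hazard = 0.02,
                                 censor_rate = 0.2, fold_up = 4,
                                 noise_sdlog = 0.2, seed = 1) {
  stopifnot(inherits(genome, "genome_spec"))
  if (n_samples < 2) stop("need at least 2 samples", call. = FALSE)
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive", call. = FALSE)
  if (!is.null(composition_prior) && sum(composition_prior > 0) < 2) {
    warning("degenerate composition prior: all mass on one program")
  }
  with_seed(seed, {
    n_genes <- genome$n_genes
    baseline <- stats::rlnorm(n_genes, 1, 1.2)
    names(baseline) <- genome$genes$gene_id
    profiles <- vapply(programs, function(p) {
      mod <- genome$modules[[p]]
      if (is.null(mod)) stop("unknown program module: ", p, call. = FALSE)
      mu <- baseline
      mu[mod] <- mu[mod] * fold_up
      mu / sum(mu)
    }, numeric(n_genes))

    # Dirichlet draws via gamma
    rdirichlet <- function(n, alpha) {
      x <- matrix(stats::rgamma(n * length(alpha),
                                shape = rep(alpha, each = n)), nrow = n)
      x / rowSums(x)
    }
    if (!is.null(composition_prior)) {
      comp <- rdirichlet(n_samples, composition_prior[programs])
    } else {
      # two-component mixture: target-high and target-low samples
      others <- setdiff(programs, target_program)
      alpha_for <- function(mu) {
        a <- stats::setNames(rep((1 - mu) * concentration / length(others),
                                 length(others)), others)
        c(stats::setNames(mu * concentration, target_program), a)[programs]
      }
      is_high <- stats::runif(n_samples) < 0.5
      comp <- matrix(NA_real_, n_samples, length(programs))
      if (any(is_high)) {
        comp[is_high, ] <- rdirichlet(sum(is_high),
                                      alpha_for(target_frac_high))
      }
      if (any(!is_high)) {
        comp[!is_high, ] <- rdirichlet(sum(!is_high),
                                       alpha_for(target_frac_low))
      }
    }
    colnames(comp) <- programs

    expr <- profiles %*% t(comp)
    expr <- expr * matrix(stats::rlnorm(length(expr), 0, noise_sdlog),
                          nrow = n_genes)
    expr <- sweep(expr, 2, colSums(expr), "/") * 1e6
    rownames(expr) <- genome$genes$gene_id
    colnames(expr) <- sprintf("bulk%03d", seq_len(n_samples))

    frac <- comp[, target_program]
    hazard <- baseline_hazard * exp(beta * frac)
    t_event <- stats::rexp(n_samples, rate = hazard)
    if (censor_rate > 0) {
      c_rate <- baseline_hazard * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n_samples, rate = c_rate)
    } else {
      t_cens <- rep(Inf, n_samples)
    }
    samples <- tibble::as_tibble(comp) |>
      dplyr::mutate(
        sample_id = colnames(expr),
        frac_target = frac,
        time = pmin(t_event, t_cens),
        event = as.integer(t_event <= t_cens),
        .before = 1
      )
    list(expr = expression_matrix(expr, "tpm"), samples = samples)
  })
}
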