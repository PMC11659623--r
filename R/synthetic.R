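#' Configuration of the synthetic mixture generator
#'
#' Shapes mirror the 16-sample whisky study the package's defaults emulate:
#' 16 samples in 2 origin classes, ~279-molecule pool with 100-200 detected
#' molecules per sample, 17 descriptors, 11 panelists each rating at most 5
#' descriptors.
#'
#' @param n_samples Number of mixture samples.
#' @param n_type_classes Number of origin classes (2).
#' @param pool_size Size of the molecule pool samples draw from.
#' @param molecules_per_sample Range (min, max) of detected molecules per
#'   sample.
#' @param n_descriptors Descriptor vocabulary size.
#' @param n_panelists Panel size.
#' @param exclusive_per_type Number of molecules planted as exclusive to each
#'   origin class (present in every sample of the class, never elsewhere).
#' @param drivers_per_descriptor Number of molecules whose presence drives
#'   each descriptor's latent intensity.
#' @param noise_rate Probability that a panelist swaps a rated descriptor for
#'   a random other one (0 = perfectly consistent panel, 1 = fully random).
#' @param rating_max Rating scale maximum.
#' @param seed Master seed; every stage derives from it deterministically.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 16, n_type_classes = 2, pool_size = 279,
                         molecules_per_sample = c(100, 200),
                         n_descriptors = 17, n_panelists = 11,
                         exclusive_per_type = 2, drivers_per_descriptor = 3,
                         noise_rate = 0.1, rating_max = 10, seed = 1) {
  stopifnot(n_samples >= 2, n_type_classes >= 2, pool_size >= 10,
            length(molecules_per_sample) == 2,
            molecules_per_sample[1] <= molecules_per_sample[2],
            n_descriptors >= 5, n_panelists >= 2,
            exclusive_per_type >= 1, drivers_per_descriptor >= 1,
            noise_rate >= 0, noise_rate <= 1, rating_max >= 1)
  need <- exclusive_per_type * n_type_classes +
    molecules_per_sample[2]
  if (pool_size < need)
    stop("pool_size too small for the exclusive molecules plus the maximum ",
         "molecules per sample", call. = FALSE)
  if (pool_size < exclusive_per_type * n_type_classes +
        drivers_per_descriptor * n_descriptors + 10)
    stop("pool_size too small for the planted exclusive and driver ",
         "molecules", call. = FALSE)
  structure(as.list(environment()), class = "synth_config")
}

# homologous volatile series (chain lengths capped at realistic sizes)
# extending the packaged vocabulary to arbitrary pool sizes
.homolog_smiles <- function(n_extra) {
  esters <- as.vector(outer(1:12, 1:10, function(k, m)
    paste0(strrep("C", k), "C(=O)O", strrep("C", m))))
  chains <- 1:16
  out <- unique(c(
    esters,
    paste0(strrep("C", chains), "O"),              # alcohols
    paste0(strrep("C", chains), "C=O"),            # aldehydes
    paste0(strrep("C", chains), "C(=O)O"),         # acids
    paste0(strrep("C", chains), "C(C)O"),          # secondary alcohols
    paste0("CC(=O)", strrep("C", chains)),         # methyl ketones
    paste0(strrep("C", chains), "C=CC=O"),         # 2-alkenals
    paste0("OC", strrep("C", chains), "O"),        # diols
    paste0("CC(C)C(=O)O", strrep("C", 1:8)),       # isobutyrates
    paste0("O=CO", strrep("C", 1:10)),             # formates
    paste0("CC(C)", strrep("C", 1:10), "O"),       # branched alcohols
    paste0("C1=CC=CC=C1", strrep("C", 1:8))))      # phenylalkanes
  out[seq_len(min(n_extra, length(out)))]
}

#' Generate a deterministic molecule pool
#'
#' Draws `pool_size` unique molecules from the packaged volatile vocabulary
#' (esters, fatty acids, phenols, terpenoids, lactones and relatives),
#' extended with programmatically generated homolog series when the
#' requested pool exceeds the vocabulary.
#'
#' @param config A [synth_config()].
#' @return A data.frame with `molecule_id` and canonical `smiles`.
#' @export
generate_pool <- function(config) {
  vocab <- read_pool(system.file("extdata", "reference_volatiles.smi",
                                 package = "mixodor"))$smiles
  if (config$pool_size > length(vocab)) {
    extra <- .homolog_smiles(3 * (config$pool_size - length(vocab)) + 50)
    vocab <- unique(c(vocab, canonicalize_smiles(extra)))
  }
  vocab <- unique(canonicalize_smiles(vocab))
  if (config$pool_size > length(vocab))
    stop("cannot assemble ", config$pool_size, " unique molecules",
         call. = FALSE)
  smiles <- withr::with_seed(config$seed,
                             sample(vocab, config$pool_size))
  data.frame(molecule_id = sprintf("M%04d", seq_along(smiles)),
             smiles = smiles, family = molecule_family(smiles),
             stringsAsFactors = FALSE)
}

#' Generate synthetic mixture compositions with planted structure
#'
#' Each sample belongs to one origin class and contains: its class's
#' exclusive molecules (always present in that class, never in the other),
#' plus a uniform-count draw from the shared pool weighted by per-molecule
#' prevalence (long-tailed, like detection frequencies in real mixtures)
#' and a mild class-affinity tilt. Each descriptor is assigned driver
#' molecules; a sample's latent intensity for a descriptor is a monotone
#' function of how many of its drivers the sample contains, on top of a
#' descriptor-specific baseline (which creates the realistic class imbalance
#' of frequent descriptors). Every (sample, molecule) gets a log-normal
#' relative peak area.
#'
#' @param config A [synth_config()].
#' @param pool Optional pool from [generate_pool()].
#' @return A list with `composition` (data.frame `sample_id`, `molecule_id`,
#'   `smiles`, `peak_area`), `type` (named class vector), `latent`
#'   (samples-by-descriptors intensity matrix), `truth` (planted exclusive
#'   and driver molecules), `pool`, `sample_ids`, `descriptors`.
#' @export
generate_mixtures <- function(config, pool = NULL) {
  if (is.null(pool)) pool <- generate_pool(config)
  withr::with_seed(config$seed + 1L, {
    ids <- sprintf("S%02d", seq_len(config$n_samples))
    types <- paste0("type", seq_len(config$n_type_classes))
    type <- setNames(rep(types, length.out = config$n_samples), ids)
    descriptors <- if (config$n_descriptors == 17) reference_descriptors()
                   else sprintf("descriptor%02d", seq_len(config$n_descriptors))

    mols <- pool$molecule_id
    if (is.null(pool$family)) pool$family <- molecule_family(pool$smiles)
    excl <- split(mols[seq_len(config$exclusive_per_type *
                                 config$n_type_classes)],
                  rep(types, each = config$exclusive_per_type))
    shared <- setdiff(mols, unlist(excl))

    # descriptors own chemically coherent molecule families (fruity esters,
    # smoky aromatics, ...): descriptors are assigned to functional-group
    # families proportionally to family size and draw their driver and
    # affiliated molecules from their family members; this is what makes a
    # sample substructure content informative about its odor profile
    # family key = functional group x molecular size class: short esters
    # and long esters smell different and form separate descriptor families
    n_heavy <- vapply(pool$smiles[match(shared, pool$molecule_id)],
                      function(sm) nchar(gsub("[^A-Z]", "", sm)),
                      numeric(1))
    size_class <- cut(n_heavy, c(0, 6, 10, Inf),
                      labels = c("small", "mid", "large"))
    fam <- setNames(paste(pool$family[match(shared, pool$molecule_id)],
                          size_class, sep = "."), shared)
    fam_sizes <- sort(table(fam), decreasing = TRUE)
    per_desc <- config$drivers_per_descriptor + 8L
    eligible <- names(fam_sizes)[fam_sizes >= per_desc]
    if (!length(eligible)) eligible <- names(fam_sizes)[1]
    quota <- pmax(1, round(config$n_descriptors *
                             as.numeric(fam_sizes[eligible]) /
                             sum(fam_sizes[eligible])))
    fam_for_desc <- rep(eligible, times = quota)[seq_len(config$n_descriptors)]
    fam_for_desc[is.na(fam_for_desc)] <- eligible[1]
    fam_members <- lapply(setNames(eligible, eligible), function(f)
      sample(names(fam)[fam == f]))
    used <- setNames(rep(0L, length(eligible)), eligible)
    drivers <- list()
    desc_affinity_list <- list()
    for (di in seq_along(descriptors)) {
      f <- fam_for_desc[di]
      take <- min(per_desc, length(fam_members[[f]]) - used[[f]])
      if (take < config$drivers_per_descriptor) {
        # family exhausted: fall back to the family with most leftovers
        f <- names(which.max(vapply(eligible, function(g)
          length(fam_members[[g]]) - used[[g]], numeric(1))))
        take <- min(per_desc, length(fam_members[[f]]) - used[[f]])
      }
      memb <- fam_members[[f]][used[[f]] + seq_len(take)]
      used[[f]] <- used[[f]] + take
      if (length(memb) < config$drivers_per_descriptor) {
        # every family exhausted (tiny pools): top up from any unassigned
        # shared molecule so each descriptor always has its full driver set
        leftover <- setdiff(shared, c(memb, unlist(drivers),
                                      unlist(desc_affinity_list)))
        stolen <- leftover[seq_len(config$drivers_per_descriptor -
                                     length(memb))]
        memb <- c(memb, stolen)
        # stolen molecules may sit in another family's unconsumed tail
        fam_members <- lapply(fam_members, function(v) setdiff(v, stolen))
      }
      drivers[[descriptors[di]]] <-
        memb[seq_len(config$drivers_per_descriptor)]
      aff <- memb[-seq_len(config$drivers_per_descriptor)]
      aff <- aff[!is.na(aff)]
      if (length(aff)) desc_affinity_list[[descriptors[di]]] <- aff
    }

    # bimodal detection prevalence as in GC-MS composition tables: a core of
    # near-ubiquitous molecules plus a sporadic majority (overall mean ~0.5,
    # matching ~150 detected of a 279 pool); mild class tilt on a third of
    # the pool
    core <- stats::runif(length(shared)) < 0.45
    prev <- setNames(ifelse(core, stats::rbeta(length(shared), 8, 2),
                            stats::rbeta(length(shared), 2, 5)), shared)
    # descriptor-level driver prevalence heterogeneity yields the skewed
    # top-5 occurrence profile seen in real panels (a few frequent
    # descriptors, a long tail of rare ones)
    # fixed, evenly spaced popularity profile (assignment shuffled per
    # seed): every dataset has a reliable moderate descriptor imbalance,
    # like the skewed top-5 occurrence tables of real panels
    driver_prev <- setNames(sample(seq(0.32, 0.66,
                                       length.out = config$n_descriptors)),
                            descriptors)
    for (d in descriptors)
      prev[drivers[[d]]] <- driver_prev[d] +
        stats::runif(config$drivers_per_descriptor, -0.05, 0.05)
    base <- setNames(rep(0L, config$n_descriptors), descriptors)

    # descriptor-affiliated sporadic molecules: odor-relevant chemistry
    # co-occurs in families, so molecules beyond the drivers co-vary with a
    # descriptor's latent intensity (this is what gives each descriptor a
    # broad molecular signature, as in real mixtures)
    rest_pool <- setdiff(shared, unlist(drivers))
    desc_affinity <- setNames(rep(NA_character_, length(rest_pool)), rest_pool)
    for (d in names(desc_affinity_list))
      desc_affinity[desc_affinity_list[[d]]] <- d
    aff_ix <- !is.na(desc_affinity)

    # class-characteristic molecules: beyond the strictly exclusive ones,
    # real origin classes differ through whole families of near-exclusive
    # compounds (e.g. peat phenols); 8 per class, frequent in their own
    # class and rare elsewhere
    nonaff <- rest_pool[!aff_ix]
    characteristic <- split(sample(nonaff, min(8 * length(types),
                                               length(nonaff) %/% 2)),
                            rep(types, length.out = min(8 * length(types),
                                                        length(nonaff) %/% 2)))

    # continuous graded driver weights (strongest first) make latent
    # intensities effectively tie-free, so each sample has a crisp
    # characteristic descriptor profile
    driver_w <- lapply(setNames(descriptors, descriptors), function(d) {
      # primary-driver dominance: one marker molecule carries most of a
      # descriptor's intensity, the others refine the ranking; odor notes
      # in mixtures are typically keyed to a character-impact compound
      w <- c(0.72, 0.18, 0.10)[seq_len(min(3, config$drivers_per_descriptor))]
      if (config$drivers_per_descriptor > 3)
        w <- c(w, rep(0.05, config$drivers_per_descriptor - 3))
      w <- w + stats::runif(config$drivers_per_descriptor, -0.02, 0.02)
      3 * config$drivers_per_descriptor * w / sum(w)  # fixed total weight
    })
    # balanced driver incidence: each driver molecule is present in a fixed
    # number of samples, split as evenly as possible across origin classes,
    # so descriptor profiles are orthogonal to type by construction (origin
    # signal comes from the exclusive molecules and the class tilt only)
    driver_ids <- unlist(drivers)
    inc <- matrix(FALSE, length(driver_ids), length(ids),
                  dimnames = list(driver_ids, ids))
    class_members <- split(ids, type[ids])
    for (m in driver_ids) {
      n_pres <- round(prev[m] * length(ids))
      k <- length(class_members)
      base_n <- n_pres %/% k
      extra_classes <- if (n_pres %% k > 0)
        sample(names(class_members), n_pres %% k) else character(0)
      for (cl in names(class_members)) {
        n_cl <- min(base_n + (cl %in% extra_classes),
                    length(class_members[[cl]]))
        if (n_cl > 0) inc[m, sample(class_members[[cl]], n_cl)] <- TRUE
      }
    }

    comp <- vector("list", length(ids))
    latent_top5 <- list()
    latent <- matrix(0, length(ids), length(descriptors),
                     dimnames = list(ids, descriptors))
    for (i in seq_along(ids)) {
      s <- ids[i]
      n_i <- sample(config$molecules_per_sample[1]:
                      config$molecules_per_sample[2], 1)
      # phase 1: driver presence fixes the latent descriptor profile
      # (graded driver contributions give finer latent resolution than a
      # flat count, so top-5 cuts tie less often)
      drivers_present <- character(0)
      for (d in descriptors) {
        hit <- inc[drivers[[d]], s]
        drivers_present <- c(drivers_present, drivers[[d]][hit])
        latent[s, d] <- min(config$rating_max,
                            base[d] + sum(driver_w[[d]][hit]))
      }
      # the sample's characteristic descriptor profile: its five highest
      # latent descriptors (seeded tie draw); this single ground-truth set
      # drives both the signature molecules below and the panel's ratings
      top_lat <- .top5_row(latent[s, ], config$seed + 3L + i)
      latent_top5[[s]] <- top_lat
      affil <- rest_pool[!is.na(desc_affinity)]
      p_in <- ifelse(desc_affinity[affil] %in% top_lat, 0.9, 0.1)
      sig_present <- affil[stats::runif(length(affil)) < p_in]
      # class-characteristic molecules: Bernoulli inclusion, frequent in
      # the sample's own class and rare otherwise
      char_all <- unlist(characteristic)
      p_char <- ifelse(char_all %in% characteristic[[type[s]]], 0.65, 0.03)
      char_present <- char_all[stats::runif(length(char_all)) < p_char]
      # non-affiliated, non-characteristic filler, weighted by prevalence
      # (affiliated and characteristic molecules never re-enter here: their
      # presence must stay coupled to the planted structure)
      filler_pool <- setdiff(rest_pool, c(affil, char_all))
      w <- prev[filler_pool]
      n_draw <- n_i - length(excl[[type[s]]]) - length(drivers_present) -
        length(sig_present) - length(char_present)
      n_draw <- max(0, min(n_draw, length(filler_pool)))
      picked <- if (n_draw > 0) sample(filler_pool, n_draw, prob = w)
                else character(0)
      protected <- c(excl[[type[s]]], drivers_present)
      present <- c(protected, sig_present, char_present, picked)
      if (length(present) > n_i) {
        # trim the signature/filler part only: the latent profile must stay
        # consistent with the drivers actually present
        loose <- c(sig_present, char_present, picked)
        present <- c(protected,
                     sample(loose, max(0, n_i - length(protected))))
      }
      comp[[i]] <- data.frame(
        sample_id = s, molecule_id = present,
        smiles = pool$smiles[match(present, pool$molecule_id)],
        peak_area = stats::rlnorm(length(present)),
        stringsAsFactors = FALSE)
    }
    list(composition = do.call(rbind, comp), type = type, latent = latent,
         truth = list(exclusive = excl, drivers = drivers, base = base,
                      characteristic = characteristic,
                      latent_top5 = latent_top5),
         pool = pool, sample_ids = ids, descriptors = descriptors)
  })
}

#' Generate a synthetic RATA panel
#'
#' Every panelist rates, per sample, the sample's five highest latent
#' descriptors (one shared seeded tie draw per sample, so a noiseless panel
#' is perfectly consistent) with intensity equal to the latent value plus
#' integer jitter, clipped into `[1, rating_max]`. With probability
#' `noise_rate` a rated descriptor is swapped for a uniformly random
#' unrated one.
#'
#' @param mixtures Output of [generate_mixtures()].
#' @param config The same [synth_config()].
#' @return A [rata_table()].
#' @export
generate_panel <- function(mixtures, config) {
  withr::with_seed(config$seed + 2L, {
    ids <- mixtures$sample_ids
    descriptors <- mixtures$descriptors
    panelists <- sprintf("panelist%02d", seq_len(config$n_panelists))
    arr <- array(0L, dim = c(length(panelists), length(ids),
                             length(descriptors)),
                 dimnames = list(panelists, ids, descriptors))
    top_latent <- mixtures$truth$latent_top5
    for (si in seq_along(ids)) {
      s <- ids[si]
      chosen0 <- top_latent[[s]]
      for (p in seq_along(panelists)) {
        chosen <- chosen0
        for (k in seq_along(chosen)) {
          if (stats::runif(1) < config$noise_rate) {
            alt <- setdiff(descriptors, chosen)
            chosen[k] <- alt[sample.int(length(alt), 1)]
          }
        }
        val <- round(mixtures$latent[s, chosen]) +
          sample(-1:1, length(chosen), replace = TRUE)
        arr[p, si, match(chosen, descriptors)] <-
          as.integer(pmin(pmax(val, 1), config$rating_max))
      }
    }
    rata_table(arr)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_pool()], [generate_mixtures()] and
#' [generate_panel()] into one dataset object consumable by
#' [run_experiment()].
#'
#' @param config A [synth_config()].
#' @return A list of class `mixture_dataset` with `composition`, `rata`,
#'   `type`, `latent`, `truth`, `pool`, `sample_ids`, `descriptors`,
#'   `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  mx <- generate_mixtures(config)
  mx$rata <- generate_panel(mx, config)
  mx$config <- config
  class(mx) <- "mixture_dataset"
  mx
}

#' @export
print.mixture_dataset <- function(x, ...) {
  cat("<mixture dataset> ", length(x$sample_ids), " samples, ",
      nrow(x$pool), " pool molecules, ", length(x$descriptors),
      " descriptors, ", dim(x$rata)[1], " panelists\n", sep = "")
  invisible(x)
}

#' Reference descriptor vocabulary
#'
#' The 17-descriptor whisky RATA vocabulary the package's defaults emulate,
#' with the published per-descriptor top-5 occurrence counts (16 samples;
#' the counts sum to 80 = 5 x 16).
#'
#' @param counts Return the named occurrence counts instead of the plain
#'   vocabulary.
#' @return Character vector of descriptors, or a named integer vector.
#' @export
reference_descriptors <- function(counts = FALSE) {
  path <- system.file("extdata", "whisky_descriptor_counts.csv",
                      package = "mixodor")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (counts) setNames(as.integer(df$top5_occurrence), df$descriptor)
  else df$descriptor
}

# top-5 of one named score vector with a seeded boundary tie draw (same rule
# as top5_labels, for a single row)
.top5_row <- function(v, seed) {
  nm <- names(v)
  ord <- order(-v, nm, method = "radix")
  cut_val <- v[ord[5]]
  sure <- nm[v > cut_val]
  tied <- nm[v == cut_val]
  need <- 5 - length(sure)
  picked <- if (length(tied) == need) tied else
    withr::with_seed(as.integer(seed), sample(tied, need))
  labs <- c(sure, picked)
  labs[order(match(labs, nm))]
}
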