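#' Scenario configuration for the founder-pulse simulator
#'
#' Describes a two-population scenario: a source population of constant
#' effective size and a sink population founded by one or more dated
#' migration pulses, each contributing a number of founder lineages drawn
#' from the standing source genealogy. Sink lineages expand star-like from
#' their founder at the pulse time (the assumption underlying rho dating),
#' or under a fast within-sink coalescent if `star_expansion = FALSE`.
#'
#' @param source_size,sink_size Sample counts for the two populations.
#' @param pulses Data frame with columns `time` (years before present) and
#'   `n_founders`; may have zero rows for a no-migration scenario (then
#'   `sink_size` must be 0).
#' @param years_per_mutation Expected years per substitution per lineage
#'   (whole-genome clock; default 2,639, matching the founder-scan clock).
#' @param ts_tv_ratio Transition:transversion ratio (default 22, a typical
#'   mitogenome value).
#' @param gamma_shape Shape of the gamma distribution of relative site
#'   rates (mean 1); smaller = more rate heterogeneity.
#' @param site_rates Optional explicit per-site relative rates for the
#'   region (overrides `gamma_shape`).
#' @param region rCRS interval simulated, default whole genome; use
#'   `c(16051, 16400)` for HVS-I.
#' @param source_ne_years Present-day coalescent timescale of the source
#'   population in years (pairwise coalescence rate `1/source_ne_years` at
#'   time 0).
#' @param source_growth_rate Exponential growth rate of the source per year:
#'   backward in time the coalescent timescale shrinks as
#'   `source_ne_years * exp(-rate * t)`, emulating a population that
#'   expanded towards the present (postglacial/Neolithic growth), so many
#'   lineages persist at the pulse times while the time to the most recent
#'   common ancestor stays moderate. Set to 0 for a constant-size source.
#' @param star_expansion Star-like post-pulse expansion in the sink.
#' @param sink_ne_years Within-sink coalescent timescale when
#'   `star_expansion = FALSE`.
#' @param source_label,sink_label Population labels written to the sample
#'   sheet.
#' @param seed Integer seed; the whole scenario (genealogy, then sequences)
#'   is reproducible from it.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(source_size = 60L, sink_size = 100L,
                            pulses = data.frame(time = c(6500, 11000),
                                                n_founders = c(12L, 12L)),
                            years_per_mutation = 2639,
                            ts_tv_ratio = 22, gamma_shape = 0.4,
                            site_rates = NULL, region = c(1L, 16569L),
                            source_ne_years = 850000,
                            source_growth_rate = 2e-4,
                            star_expansion = TRUE, sink_ne_years = 3000,
                            source_label = "mainland",
                            sink_label = "taiwan", seed = 1L) {
  stopifnot(source_size >= 1L, sink_size >= 0L)
  if (nrow(pulses)) {
    stopifnot(all(c("time", "n_founders") %in% names(pulses)),
              all(pulses$time > 0), all(pulses$n_founders >= 1L))
    if (anyDuplicated(pulses$time)) {
      stop("pulse times must be distinct", call. = FALSE)
    }
  } else if (sink_size > 0L) {
    stop("sink_size > 0 requires at least one pulse", call. = FALSE)
  }
  stopifnot(years_per_mutation > 0, ts_tv_ratio > 0, gamma_shape > 0,
            source_ne_years > 0, sink_ne_years > 0, source_growth_rate >= 0)
  region <- as.integer(region)
  stopifnot(region[1] >= 1L, region[2] <= 16569L, region[1] <= region[2])
  if (!is.null(site_rates)) {
    stopifnot(length(site_rates) == region[2] - region[1] + 1L,
              all(site_rates > 0))
  }
  structure(list(source_size = as.integer(source_size),
                 sink_size = as.integer(sink_size),
                 pulses = pulses[order(pulses$time), , drop = FALSE],
                 years_per_mutation = years_per_mutation,
                 ts_tv_ratio = ts_tv_ratio, gamma_shape = gamma_shape,
                 site_rates = site_rates, region = region,
                 source_ne_years = source_ne_years,
                 source_growth_rate = source_growth_rate,
                 star_expansion = isTRUE(star_expansion),
                 sink_ne_years = sink_ne_years,
                 source_label = source_label, sink_label = sink_label,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# run expr under a given seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a genealogy under a founder-pulse scenario
#'
#' Backward-in-time simulation: source lineages coalesce under a
#' constant-size coalescent; at each pulse time the stipulated number of
#' founder lineages is drawn (without replacement) from the lineages of the
#' standing source genealogy, and the pulse's sink samples attach to their
#' founder -- as a star at the pulse time by default. Sink samples are
#' divided as evenly as possible among pulses, and within a pulse among its
#' founders. Reproducible from `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return An object of class `sim_genealogy`: node table (`id`, `time`,
#'   `parent`), root id, tip ids, and a `truth` data frame giving each
#'   sample's ancestry (`source` or `pulse<k>`), founder id and pulse time.
#' @export
simulate_genealogy <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  .with_seed(config$seed, .simulate_genealogy_impl(config))
}

.simulate_genealogy_impl <- function(config) {
  src_ids <- sprintf("S%03d", seq_len(config$source_size))
  snk_ids <- if (config$sink_size > 0L)
    sprintf("T%03d", seq_len(config$sink_size)) else character(0)

  id <- c(src_ids, snk_ids)
  time <- rep(0, length(id))
  parent <- rep(NA_character_, length(id))
  new_node <- local({
    counter <- 0L
    function(t) {
      counter <<- counter + 1L
      id <<- c(id, sprintf("A%04d", counter))
      time <<- c(time, t)
      parent <<- c(parent, NA_character_)
      id[length(id)]
    }
  })
  set_parent <- function(child, p) parent[match(child, id)] <<- p

  # sink sample assignment: pulses get even shares, founders within a pulse
  # get even shares in randomised order
  npulse <- nrow(config$pulses)
  truth <- data.frame(sample_id = id, ancestry = "source",
                      pulse_time = NA_real_, founder = NA_character_,
                      stringsAsFactors = FALSE)
  pulse_members <- vector("list", npulse)
  if (config$sink_size > 0L) {
    pulse_of <- rep_len(seq_len(npulse), config$sink_size)
    pulse_of <- pulse_of[sample.int(length(pulse_of))]
    for (p in seq_len(npulse)) {
      pulse_members[[p]] <- snk_ids[pulse_of == p]
    }
  }

  active <- src_ids
  t_cur <- 0
  ne0 <- config$source_ne_years
  r <- config$source_growth_rate

  # waiting time to the next coalescence among k lineages when the
  # coalescent timescale shrinks backward in time as ne0 * exp(-r t):
  # inverse of the integrated hazard, closed form for r > 0
  next_wait <- function(k, t0) {
    e <- rexp(1)
    pr <- k * (k - 1) / 2
    if (r == 0) return(e * ne0 / pr)
    log(exp(r * t0) + e * ne0 * r / pr) / r - t0
  }

  coalesce_until <- function(t_stop) {
    repeat {
      k <- length(active)
      if (k <= 1L) { t_cur <<- t_stop; return(invisible()) }
      wait <- next_wait(k, t_cur)
      if (!is.finite(t_stop) || t_cur + wait < t_stop) {
        t_cur <<- t_cur + wait
        pair <- sample(k, 2L)
        anc <- new_node(t_cur)
        set_parent(active[pair[1]], anc)
        set_parent(active[pair[2]], anc)
        active <<- c(active[-pair], anc)
      } else {
        t_cur <<- t_stop
        return(invisible())
      }
    }
  }

  founder_rows <- NULL
  for (p in seq_len(npulse)) {
    T_p <- config$pulses$time[p]
    n_f <- config$pulses$n_founders[p]
    coalesce_until(T_p)
    if (n_f > length(active)) {
      stop(sprintf(
        "pulse at %g years requests %d founders but only %d source lineages remain",
        T_p, n_f, length(active)), call. = FALSE)
    }
    chosen <- sample(length(active), n_f)
    members <- pulse_members[[p]]
    f_of <- if (length(members)) {
      shares <- rep_len(seq_len(n_f), length(members))
      shares[sample.int(length(shares))]
    } else integer(0)
    for (f in seq_len(n_f)) {
      fid <- sprintf("P%d.%d", p, f)
      fnode <- new_node(T_p)
      lineage <- active[chosen[f]]
      set_parent(lineage, fnode)
      active[chosen[f]] <- fnode
      kids <- members[f_of == f]
      truth$ancestry[match(kids, truth$sample_id)] <- paste0("pulse", p)
      truth$pulse_time[match(kids, truth$sample_id)] <- T_p
      truth$founder[match(kids, truth$sample_id)] <- fid
      founder_rows <- rbind(founder_rows,
                            data.frame(founder = fid, node = fnode,
                                       pulse = p, time = T_p,
                                       n_samples = length(kids),
                                       stringsAsFactors = FALSE))
      if (!length(kids)) next
      if (config$star_expansion) {
        for (kd in kids) set_parent(kd, fnode)
      } else {
        grp <- kids
        tg <- 0
        repeat {
          kk <- length(grp)
          if (kk <= 1L) break
          wait <- rexp(1, rate = kk * (kk - 1) / 2 / config$sink_ne_years)
          if (tg + wait >= T_p) break
          tg <- tg + wait
          pr <- sample(kk, 2L)
          anc <- new_node(tg)
          set_parent(grp[pr[1]], anc)
          set_parent(grp[pr[2]], anc)
          grp <- c(grp[-pr], anc)
        }
        for (g in grp) set_parent(g, fnode)
      }
    }
  }
  coalesce_until(Inf)
  root <- active[1]

  truth <- truth[match(c(src_ids, snk_ids), truth$sample_id), ]
  rownames(truth) <- NULL
  structure(list(nodes = data.frame(id = id, time = time, parent = parent,
                                    stringsAsFactors = FALSE),
                 root = root, tips = c(src_ids, snk_ids), truth = truth,
                 founders = founder_rows, config = config),
            class = "sim_genealogy")
}

#' @export
print.sim_genealogy <- function(x, ...) {
  cat(sprintf(
    "<sim_genealogy> %d tips (%d source, %d sink), root age %.0f years, %d founder lineage(s)\n",
    length(x$tips), x$config$source_size, x$config$sink_size,
    x$nodes$time[match(x$root, x$nodes$id)],
    if (is.null(x$founders)) 0L else nrow(x$founders)))
  invisible(x)
}

#' Write a simulated genealogy in Newick format
#'
#' @param genealogy A `sim_genealogy`.
#' @param path Optional output file.
#' @return The Newick string (branch lengths in years).
#' @export
genealogy_newick <- function(genealogy, path = NULL) {
  nd <- genealogy$nodes
  kids <- split(nd$id, factor(nd$parent, levels = nd$id))
  tm <- setNames(nd$time, nd$id)
  rec <- function(v, plen) {
    k <- kids[[v]]
    body <- if (length(k)) {
      paste0("(", paste(vapply(k, function(x)
        rec(x, tm[[v]] - tm[[x]]), character(1)), collapse = ","), ")")
    } else ""
    paste0(body, v, ":", format(plen, scientific = FALSE))
  }
  nwk <- paste0(rec(genealogy$root, 0), ";")
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}

#' Evolve sequences along a simulated genealogy
#'
#' Places substitutions as a Poisson process along every branch (expected
#' one per `years_per_mutation` lineage-years), drawing positions by the
#' per-site relative rates and choosing transition versus transversion by
#' the configured ratio. The reference is the root state; recurrent and
#' back mutations can occur naturally. Uses the sub-stream `config$seed +
#' 1`, so a full scenario run is reproducible from the single scenario
#' seed.
#'
#' @param genealogy A `sim_genealogy`.
#' @param config The [scenario_config()] used to simulate it.
#' @param reference Reference genome string (root state).
#' @return A list with `sequences` (named character vector over the
#'   region), `truth` (data frame of true variants per sample:
#'   `sample_id`, `position`, `ref`, `alt`, `kind`) and `site_rates`.
#' @export
evolve_sequences <- function(genealogy, config = genealogy$config,
                             reference = mito_reference()) {
  stopifnot(inherits(genealogy, "sim_genealogy"))
  .with_seed(config$seed + 1L, .evolve_impl(genealogy, config, reference))
}

.evolve_impl <- function(genealogy, config, reference) {
  region <- config$region
  L <- region[2] - region[1] + 1L
  rates <- if (!is.null(config$site_rates)) config$site_rates
           else rgamma(L, shape = config$gamma_shape,
                       rate = config$gamma_shape)
  pr <- rates / sum(rates)
  root_seq <- strsplit(substr(reference, region[1], region[2]), "",
                       fixed = TRUE)[[1]]
  nd <- genealogy$nodes
  kids <- split(nd$id, factor(nd$parent, levels = nd$id))
  tm <- setNames(nd$time, nd$id)
  p_ts <- config$ts_tv_ratio / (config$ts_tv_ratio + 1)
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  tv_partners <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

  seqs <- list()
  founder_nodes <- if (!is.null(genealogy$founders))
    genealogy$founders$node else character(0)
  founder_seqs <- list()
  # iterative preorder DFS carrying the evolving sequence
  stack <- list(list(id = genealogy$root, seq = root_seq))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top$id
    sq <- top$seq
    if (!identical(v, genealogy$root)) {
      blen <- tm[[nd$parent[match(v, nd$id)]]] - tm[[v]]
      nmut <- rpois(1, blen / config$years_per_mutation)
      if (nmut > 0) {
        pos <- sample.int(L, nmut, replace = TRUE, prob = pr)
        for (j in seq_len(nmut)) {
          b <- sq[pos[j]]
          sq[pos[j]] <- if (runif(1) < p_ts) ts_partner[[b]]
                        else sample(tv_partners[[b]], 1L)
        }
      }
    }
    if (v %in% genealogy$tips) {
      seqs[[v]] <- paste(sq, collapse = "")
    }
    if (v %in% founder_nodes) {
      founder_seqs[[v]] <- paste(sq, collapse = "")
    }
    for (w in kids[[v]]) {
      stack[[length(stack) + 1L]] <- list(id = w, seq = sq)
    }
  }
  sequences <- unlist(seqs)[genealogy$tips]

  truth <- do.call(rbind, lapply(genealogy$tips, function(s) {
    sc <- strsplit(sequences[[s]], "", fixed = TRUE)[[1]]
    d <- which(sc != root_seq)
    if (!length(d)) return(NULL)
    data.frame(sample_id = s, position = region[1] + d - 1L,
               ref = root_seq[d], alt = sc[d],
               kind = .sub_kind(root_seq[d], sc[d]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(sample_id = character(), position = integer(),
                        ref = character(), alt = character(),
                        kind = character(), stringsAsFactors = FALSE)
  }
  list(sequences = sequences, truth = truth, site_rates = rates,
       founder_sequences = if (length(founder_seqs)) unlist(founder_seqs))
}

#' Built-in simulation scenarios
#'
#' @return Named list of [scenario_config()] objects: `two-pulse-taiwan`
#'   (pulses at 6,500 and 11,000 years, 12 founders each, 100 sink
#'   samples), `single-founder` (one pulse at 6,500 years with a single
#'   founder) and `no-migration` (source only).
#' @export
scenario_registry <- function() {
  list(
    "two-pulse-taiwan" = scenario_config(
      source_size = 60L, sink_size = 100L,
      pulses = data.frame(time = c(6500, 11000), n_founders = c(12L, 12L)),
      seed = 1640L),
    "single-founder" = scenario_config(
      source_size = 30L, sink_size = 20L,
      pulses = data.frame(time = 6500, n_founders = 1L), seed = 164L),
    "no-migration" = scenario_config(
      source_size = 30L, sink_size = 0L,
      pulses = data.frame(time = numeric(0), n_founders = integer(0)),
      seed = 16L))
}

#' Materialise a bundled scenario as a dataset directory
#'
#' Simulates a registered scenario and writes `sequences.fasta`,
#' `samples.tsv` (sample sheet), `truth.tsv` (true variants),
#' `ancestry.tsv` (per-sample ancestry truth), `genealogy.nwk` and
#' `config.json` into a directory. Regenerating a fixture with its recorded
#' seed reproduces the files byte for byte.
#'
#' @param name Scenario name; see [scenario_registry()].
#' @param dir Output directory (created if needed).
#' @param seed Optional seed override.
#' @return Invisibly, a list with the file paths, the config and the truth
#'   tables.
#' @export
make_fixture <- function(name, dir = tempfile("fixture_"), seed = NULL) {
  reg <- scenario_registry()
  if (!name %in% names(reg)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  config <- reg[[name]]
  if (!is.null(seed)) config$seed <- as.integer(seed)
  gen <- simulate_genealogy(config)
  ev <- evolve_sequences(gen, config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(fasta = file.path(dir, "sequences.fasta"),
                samples = file.path(dir, "samples.tsv"),
                truth = file.path(dir, "truth.tsv"),
                ancestry = file.path(dir, "ancestry.tsv"),
                newick = file.path(dir, "genealogy.nwk"),
                config = file.path(dir, "config.json"))
  .write_fasta(ev$sequences, paths$fasta)
  sheet <- data.frame(
    sample_id = gen$tips,
    population = ifelse(gen$truth$ancestry == "source",
                        config$source_label, config$sink_label),
    stringsAsFactors = FALSE)
  write.table(sheet, paths$samples, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ev$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gen$truth, paths$ancestry, sep = "\t", quote = FALSE,
              row.names = FALSE)
  genealogy_newick(gen, paths$newick)
  cfg <- unclass(config)
  cfg$pulses <- as.list(config$pulses)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(paths = paths, config = config, genealogy = gen,
                 sequences = ev$sequences, truth = ev$truth,
                 ancestry = gen$truth))
}
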