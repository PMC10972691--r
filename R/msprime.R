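# Bridge to the msprime tree-sequence simulator (via the system Python
# interpreter) for simulations that need recombination along a sequence:
# blocks linked within bootstrap chunks, and the gene-conversion-only null.
# Unlinked-block simulation is native (see sim_tally / sim_dataset).

find_python <- function() {
  opt <- getOption("invdemog.python")
  if (!is.null(opt)) return(opt)
  for (cand in c("python3", "python")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(unname(p))
  }
  stop("no python interpreter on PATH; linked-sequence simulation needs ",
       "python with msprime (set options(invdemog.python = ...))",
       call. = FALSE)
}

# run inst/python/sim_linked.py on a JSON config, return the output table
run_msprime <- function(cfg) {
  script <- system.file("python", "sim_linked.py", package = "invdemog")
  if (!nzchar(script)) stop("bundled msprime script not found", call. = FALSE)
  cfg_file <- tempfile(fileext = ".json")
  out_file <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(cfg_file, out_file)), add = TRUE)
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA)
  log <- suppressWarnings(system2(find_python(), c(script, cfg_file, out_file),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(log, "status") %||% 0L
  if (status != 0L || !file.exists(out_file)) {
    stop("msprime backend failed:\n", paste(log, collapse = "\n"),
         call. = FALSE)
  }
  tibble::as_tibble(utils::read.table(out_file, header = TRUE, sep = "\t"))
}

demography_cfg <- function(model, params) {
  p <- validate_params(params, model)
  list(ne_a = p$ne_a, ne_b = p$ne_b, ne_anc = p$ne_anc, t = p$t,
       m = p$m %||% 0,
       direction = switch(model, div = "none", im_ab = "ab", im_ba = "ba"))
}
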