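# Cross-tool SASA oracle: python biotite's independent Shrake-Rupley
# implementation, run on the same element radii and probe.  Returns a named
# per-residue vector ("chain:resno") of accessible areas.
biotite_res_sasa <- function(pdb_file, chains = NULL, points = 2000) {
  py <- Sys.which("python")
  stopifnot(nzchar(py))
  script <- tempfile(fileext = ".py")
  out <- tempfile(fileext = ".tsv")
  writeLines(sprintf('
import numpy as np
import biotite.structure as struc
import biotite.structure.io.pdb as pdbio
f = pdbio.PDBFile.read(%s)
arr = f.get_structure(model=1)
arr = arr[arr.element != "H"]
chains = %s
if chains:
    arr = arr[np.isin(arr.chain_id, chains)]
radii = {"C":1.70,"N":1.55,"O":1.52,"S":1.80,"P":1.80}
vr = np.array([radii.get(e, 1.70) for e in arr.element])
sasa = struc.sasa(arr, probe_radius=1.4, point_number=%d, vdw_radii=vr)
with open(%s, "w") as fh:
    for ch, rn in sorted(set(zip(arr.chain_id, arr.res_id))):
        m = (arr.chain_id == ch) & (arr.res_id == rn)
        fh.write("%%s:%%d\\t%%.6f\\n" %% (ch, rn, float(np.nansum(sasa[m]))))
', deparse(pdb_file),
   if (is.null(chains)) "None" else
     paste0("[", paste(sprintf('"%s"', chains), collapse = ","), "]"),
   points, deparse(out)), script)
  status <- system2(py, script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(out))
    stop("biotite oracle failed: ", paste(status, collapse = "\n"))
  tab <- utils::read.delim(out, header = FALSE,
                           col.names = c("key", "sasa"))
  stats::setNames(tab$sasa, tab$key)
}
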