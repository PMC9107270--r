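# mmclone

Clonality and phylogeny analysis of multiple meningiomas from per-lesion
somatic call sets.

About 10% of meningioma patients harbor several spatially separated tumors.
Whether those tumors descend from one founding clone (monoclonal origin,
followed by branched evolution) or arose independently cannot be read from
imaging or histology — but it can be read from somatic genomics: monoclonal
lesions share truncal alterations, independent lesions do not. `mmclone`
implements that analysis for neuro-oncology genomics groups working with
standard tumor-vs-normal exome calls. Given per-lesion SNV/INDEL tables and
copy-number/allelic segment tables it:

* applies the post-calling filters (gnomAD population AF > 0.01 excluded,
  non-coding impacts excluded, VAF below the contamination rate excluded);
* calls arm/chromosome-level deletion, amplification and LOH events and
  partitions all alterations into shared-by-all / partially shared /
  private;
* classifies each tumor's molecular subtype (*NF2*-loss — somatic *NF2*
  mutation and/or chromosome 22 deletion — vs non-*NF2*);
* classifies each patient as **monoclonal** (≥ 1 driver feature shared by
  every lesion: an identical driver-panel mutation or a shared CNV/LOH
  event) or **independent**;
* estimates clonal fractions two ways and checks their concordance,
  with VAF = c/2 for a heterozygous diploid mutation (so c = 2·VAF) and
  MAF = (1 − c)/2 for a copy-neutral LOH segment (so c = 1 − 2·MAF);
* infers a per-patient phylogeny: binary alteration matrix → Manhattan
  distances → Saitou–Nei neighbor joining, rooted on an all-zero germline
  outgroup, serialized as canonical Newick.

A simulator (`simulate_patient()`) generates multi-lesion cohorts with
known clonal ground truth under monoclonal-branched and independent
scenarios, with binomial read-depth noise on VAFs, so the whole chain is
testable without access-controlled patient data.

## Worked example

The package ships a six-patient cohort fixture encoding the per-tumor
alterations of a published multiple-meningioma series (15 tumors and one
uninvolved dura specimen):

```r
library(mmclone)

report <- run_pipeline(build_inpaper_fixture())
report
#> <cohort report>
#>   tumors: 15 (11 NF2-loss, 4 non-NF2)
#>   patients with verdict: 6 (5 monoclonal, 1 independent)
```

Eleven of the fifteen tumors are *NF2*-loss; five of the six patients are
monoclonal, and the sixth (one *TRAF7*-mutant and one *POLR2A*-mutant
tumor, nothing shared) is independent. Patient S5 is the interesting case:
two non-*NF2* tumors that share only a chromosome X LOH segment while
carrying two *different* *TRAF7* mutations — branched evolution in a
non-*NF2* patient. The two clonal-fraction estimators agree per lesion:

```r
subset(report$clonal_fractions, patient_id == "S5")
#>    patient_id lesion_id loh_event  maf cf_from_maf                      snv  vaf cf_from_vaf concordant
#> 25         S5     S5-T1 CNV:loh:X 0.30        0.40 SNV:TRAF7:16:2216000:A>G 0.22        0.44       TRUE
#> 26         S5     S5-T2 CNV:loh:X 0.11        0.78 SNV:TRAF7:16:2224000:T>G 0.40        0.80       TRUE
```

i.e. the chrX event and the *TRAF7* mutation sit in the same ~40% clone in
S5-T1 and the same ~80% clone in S5-T2. The patient's tree places both
tumors in one clade against the germline root:

```r
report$trees$S5
#> [1] "(germline:1,(S5-T1:1,S5-T2:1):0);"
```

File-based workflows use a JSON/YAML manifest of per-lesion tables
(`run_pipeline("manifest.json")`); `write_fixture()` writes any case —
simulated or constructed — into that layout. A thin command-line front end
is installed at `inst/scripts/mmclone.R`
(`Rscript mmclone.R run|simulate|fixtures ...`).

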