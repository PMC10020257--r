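# Default relative-risk parameter set.
#
# These are documented, non-canonical approximations: family-history RRs in
# the flavor of the Collaborative Group pooled analysis, and plausible
# density/BMI log-linear slopes.  All values are configuration, not constants;
# replace this file to drop in a fitted parameter set.
model:
  lifetime_max_age: 85
family_history:
  categories:
    - {n_fdr: "0",  age_dx: "any",  n_sdr: "0",   rr: 1.0, weight: 0.66}
    - {n_fdr: "0",  age_dx: "any",  n_sdr: "1+",  rr: 1.3, weight: 0.20}
    - {n_fdr: "1",  age_dx: "<50",  n_sdr: "any", rr: 2.3, weight: 0.04}
    - {n_fdr: "1",  age_dx: ">=50", n_sdr: "any", rr: 1.8, weight: 0.08}
    - {n_fdr: "2+", age_dx: "any",  n_sdr: "any", rr: 2.9, weight: 0.02}
density:
  mode: continuous
  continuous:
    slope: 0.02       # log-RR per percent density
    reference: 25     # percent density with RR 1 before centering
  categorical:
    - {label: "<25%",  rr: 0.8, weight: 0.6}
    - {label: ">=25%", rr: 1.5, weight: 0.4}
bmi:
  pre:  {slope: -0.02, reference: 25}   # log-RR per kg/m^2, premenopausal
  post: {slope:  0.03, reference: 25}   # log-RR per kg/m^2, postmenopausal
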