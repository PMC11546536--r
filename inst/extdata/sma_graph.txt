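# Causal DAG for a motor-function hybrid trial in spinal muscular
# atrophy: baseline covariates (enrollment age, SMA type, scoliosis,
# baseline motor score MFM0) cause the 12-month motor score MFM12;
# treatment A acts on MFM12; covariates are inter-related.
Age: covariate
Type: covariate
Scoliosis: covariate
MFM0: covariate
A: treatment
MFM12: outcome
Age -> MFM12
Type -> MFM12
Scoliosis -> MFM12
MFM0 -> MFM12
A -> MFM12
Age -> MFM0
Type -> MFM0
Age -> Scoliosis
Type -> Scoliosis
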