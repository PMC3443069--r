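dataset_id	geo_id	target_set_id	disease	tissue
d01	GSE1297	hsa05010	Alzheimer's disease	Hippocampal CA1
d02	GSE5281	hsa05010	Alzheimer's disease	Brain, entorhinal cortex
d03	GSE5281	hsa05010	Alzheimer's disease	Brain, hippocampus
d04	GSE5281	hsa05010	Alzheimer's disease	Brain, primary visual cortex
d05	GSE20153	hsa05012	Parkinson's disease	Lymphoblasts
d06	GSE20291	hsa05012	Parkinson's disease	Postmortem brain putamen
d07	GSE8762	hsa05016	Huntington's disease	Lymphocytes (blood)
d08	GSE4107	hsa05210	Colorectal cancer	Mucosa
d09	GSE8671	hsa05210	Colorectal cancer	Colon
d10	GSE9348	hsa05210	Colorectal cancer	Colon
d11	GSE14762	hsa05211	Renal cancer	Kidney
d12	GSE781	hsa05211	Renal cancer	Kidney
d13	GSE15471	hsa05212	Pancreatic cancer	Pancreas
d14	GSE16515	hsa05212	Pancreatic cancer	Pancreas
d15	GSE19728	hsa05214	Glioma	Brain
d16	GSE21354	hsa05214	Glioma	Brain, spine
d17	GSE6956	hsa05215	Prostate cancer	Prostate
d18	GSE6956	hsa05215	Prostate cancer	Prostate
d19	GSE3467	hsa05216	Thyroid cancer	Thyroid
d20	GSE3678	hsa05216	Thyroid cancer	Thyroid
d21	GSE9476	hsa05221	Acute myeloid leukemia	Blood, bone marrow
d22	GSE18842	hsa05223	Non-small cell lung cancer	Lung
d23	GSE19188	hsa05223	Non-small cell lung cancer	Lung
d24	GSE3585	hsa05414	Dilated cardiomyopathy	Heart
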