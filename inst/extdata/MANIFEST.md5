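8cf7db8dfc7a0ae2254bacd8f499c834 hsa_pir.tsv
1e233f0827bcc1c73a1d98a7dec67607 hsa_ccr.tsv
c4b1832bc4ad31b7a44743e5f50b97cf soe_ccr.tsv
509489385eb616f3b15a0d736e3eea5d hsa_cut_reconstructed.tsv
78def120fcdd47cdebed0a07b7c9cb89 ancestral_platyrrhini.txt
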