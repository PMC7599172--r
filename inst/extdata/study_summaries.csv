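study,species,transposon,target_motif,donor,targets_1e3,unique_insertions_1e3,targets_without_insertion_1e3,total_reads_1e6,max_reads_1e3,auc
CaAcDs,C_albicans,AcDs,none,genome,NA,588.97,NA,84.16,3254.83,0.99
ScAcDs,S_cerevisiae,AcDs,none,plasmid,NA,514.89,NA,47.10,2210.55,0.99
ScHermes,S_cerevisiae,Hermes,TNNNNA,plasmid,1154.84,444.41,924.56,18.22,11.72,0.97
SpHermes,S_pombe,Hermes,TNNNNA,plasmid,1302.41,382.82,1110.20,23.92,2355.61,0.96
CaPB,C_albicans,PiggyBac,TTAA,genome,120.27,191.49,10.69,32.58,1301.82,0.94
SpPB,S_pombe,PiggyBac,TTAA,genome,111.37,37.50,79.09,6.14,48.31,0.79
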