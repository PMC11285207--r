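>N_DOMAIN synthetic flagellin N-terminal (D0-D1) template, 135 aa; tlr5_motif 89-110; hinge 31-52
DSADLPKFLFPNNINSQYDTGIIKHWRTYYNNVVAQRAGRGPQLQGQNEVAQLTSPQAMRGTERRFSRDLKQIQDTVVRNSKSKTDVMLITEYNTQTSKQGLGTDSRTINGNIAQDVHLEKQYKSFTDGDRIRNH
>C_DOMAIN synthetic flagellin C-terminal (D0) template, 85 aa; allosteric 30-64
AMKSFKKSLYAIISNLGSPMETLSKAAEQVLLDSGSQYGAQQKTDKLIMFGKAVTAQENTPELVKRAPDDQPTNLTSEPNRNSFK
>C_ALLOSTERIC_SILENT synthetic silent-lineage allosteric segment, 35 aa
ANNHVGIILVVEAELQQNRGMNAAEAKASNGEPRV
>N_EVADER_LINEAGE synthetic evader-lineage N-terminal domain, 135 aa (TLR5 motif diverged)
DSNKLPKFLFPNNINSQYQTHICKHWRTSYNNAFAQRAGMMPQLQGKNEKAQLTSAQAMRPWKRRFSCDLKLIQDGVVRNIKQGTDVMLYEEEFTQTAKSGIRQMPRWNSGNIAQDVHLEQQYFSFIPGDRIREE
>C_EVADER_LINEAGE synthetic evader-lineage C-terminal domain, 85 aa
AYKSFKTCLYAIISNLVSPMETKADAAEPVFCHEGSQYGAQQVTDDLIMDPKAVTAQENTMALVKRAPDDQPTNVTCVPVRNHYG
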