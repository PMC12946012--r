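connection_id,species,cell_class,category
hFS_01,human,FS,increase
hFS_02,human,FS,increase
hFS_03,human,FS,increase
hFS_04,human,FS,increase
hFS_05,human,FS,increase
hFS_06,human,FS,increase
hFS_07,human,FS,decrease
hFS_08,human,FS,decrease
hFS_09,human,FS,no_change
hFS_10,human,FS,no_change
hFS_11,human,FS,no_change
hNF_01,human,nonFS,increase
hNF_02,human,nonFS,increase
hNF_03,human,nonFS,decrease
hNF_04,human,nonFS,no_change
hNF_05,human,nonFS,no_change
hNF_06,human,nonFS,no_change
hNF_07,human,nonFS,no_change
hNF_08,human,nonFS,no_change
hNF_09,human,nonFS,no_change
hNF_10,human,nonFS,no_change
hNF_11,human,nonFS,no_change
hNF_12,human,nonFS,no_change
hNF_13,human,nonFS,no_change
rFS_01,rat,FS,increase
rFS_02,rat,FS,increase
rFS_03,rat,FS,increase
rFS_04,rat,FS,increase
rFS_05,rat,FS,increase
rFS_06,rat,FS,decrease
rFS_07,rat,FS,no_change
rFS_08,rat,FS,no_change
rFS_09,rat,FS,no_change
rFS_10,rat,FS,no_change
rFS_11,rat,FS,no_change
rFS_12,rat,FS,no_change
rFS_13,rat,FS,no_change
rFS_14,rat,FS,no_change
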