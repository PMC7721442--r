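,,PROT_A,PROT_A,PROT_A,PROT_A,PROT_A,PROT_A,PROT_A,PROT_A,PROT_A,PROT_B,PROT_B,PROT_B,PROT_B,PROT_B,PROT_B
,,AQLSTK01,AQLSTK02,AQLSTK03,AQLSTK04,AQLSTK05,AQLSTK06,AQLSTK07,AQLSTK08,AQLSTK09,VLDNR01,VLDNR02,VLDNR03,VLDNR04,VLDNR05,VLDNR06
t0,reference,1616076,1494637,398664,2473366,1995181,5029423,2050625,969925,4924257,224418,173614,237828,182228,927436,360833
t4,treated,1577288,1452993,302870,2402628,1951646,5265548,1876785,932729,5215966,212883,175678,245794,179875,888055,353635
t8,treated,1577858,1530562,196814,2566493,1931823,4984662,1431329,981737,5080968,219785,164627,237569,179378,951704,345803
t10,treated,1615489,1540200,78806,2486969,2107954,4796682,1096418,943729,4886003,210250,178355,236778,181045,930629,349839
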