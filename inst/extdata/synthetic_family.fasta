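; synthetic paralog family, generator seed 17, L=70, k=10
>A_sp1 species=sp1;group=A
WGYKPEMDIPATIWVCFLWSDYGNREGDCTKLPDNHCRWVMFLKKHGMRYFWAHDMIDNY
MHKWNRFMYA
>A_sp2 species=sp2;group=A
WGAKPEMDIPATIQVCFDWSDYGNAEGDCTKLPDCGCRWVMFLKKHGMRYQWAFDMHDNY
CHEWPRFMYA
>A_sp3 species=sp3;group=A
WGAKPEMDIPATIQVCFDWSDYGMAEFDCTKLPDCGCRWVMFLKKYGMRYFWAHDMIDNY
CHAWNRFMYA
>B_sp1 species=sp1;group=B
WGADPEMRIPATIQVCFDWSRYGNAEGRCTDLPKCGCDWVMFLKDHGMDYFWAHKMIDNY
CHKWNDFMYA
>B_sp2 species=sp2;group=B
WGADPEMRIYATIQVCFDWSRYGNAEGRCTDLPKCGCRWVMFLKDHGMDYFWAEKMIDNY
CHKWNDFMYA
>B_sp3 species=sp3;group=B
WGDDPEMRIPATIQVMFDWSRYGNAEGRCTDLPKCGCRWVMFLKDHGMDYFWAHKMIDIY
CHIWNDFMYA
>outgroup species=;group=outgroup
RGAKPEMDIPATIQVCFDWSDYGNMEGDCTKLPDCGCRWVMFLKKHGMRYFWAHDMIDNY
CHKWNRFMYA
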