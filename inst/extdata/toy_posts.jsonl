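{"id":"p01","author":"u1","created_utc":1609459200,"link_flair_text":"Symptoms","body":"started famotidine and cetirizine last week, famotidine twice daily, plus magnesium at night"}
{"id":"p02","author":"u2","created_utc":1609459260,"link_flair_text":"Symptoms","body":"my stack: zyrtec every morning, famotidine with dinner, magnesium glycinate before bed"}
{"id":"p03","author":"u3","created_utc":1609459320,"link_flair_text":"Question","body":"anyone combining ceterizine with famotidine? adding magnesium helped my sleep a lot"}
{"id":"p04","author":"u4","created_utc":1609459380,"link_flair_text":"Recovery","body":"cetirizine hydrochloride plus famotidine finally calmed the flares. magnesium stays in my routine"}
{"id":"p05","author":"u5","created_utc":1609459440,"link_flair_text":"Question","body":"never took famotidine myself. melatonin helps me sleep through the night"}
{"id":"p06","author":"u1","created_utc":1609459500,"link_flair_text":"Symptoms","body":"wrote up my recovery log here\thttps://example.org/timeline\n\nstill mostly resting and pacing"}
{"id":"p07","author":"u6","created_utc":1609459560,"link_flair_text":"Vent","body":"eighteen months of this. so tired of crashing after every small walk"}
{"id":"p08","author":"u7","created_utc":1609459620,"link_flair_text":"Update","body":"cut out ethanol completely this month, sleeping a little better now"}
{"id":"p09","author":"u8","created_utc":1609459680,"link_flair_text":"Humor","body":"my personality is 50 percent aspirin jokes at this point"}
{"id":"p10","author":"u9","created_utc":1609459740,"link_flair_text":null,"body":"zinc lozenges did nothing for me but posting untagged anyway"}
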