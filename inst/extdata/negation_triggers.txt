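# Negation trigger lists, Negex style. PRE: triggers scope forward over the
# following tokens, POST: backward, PSEUDO: suppresses a PRE trigger that it
# prefixes (e.g. "not only" neutralises "not").
PRE: no
PRE: not
PRE: never
PRE: without
PRE: stopped
PRE: stopped taking
PRE: quit
PRE: never took
PRE: cannot
PRE: can't
PRE: don't take
PRE: didn't take
PRE: no longer
PRE: avoid
PRE: avoided
POST: free
PSEUDO: not only
PSEUDO: no increase
PSEUDO: not necessarily
PSEUDO: no doubt
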